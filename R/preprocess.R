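# Filtering, binarization, three-class labeling and maximum-intensity
# projection: the raster preprocessing that every structural parameter in
# this package consumes. Semantics follow the Fiji-style workflow: disc
# mean filter with edge replication, >= thresholding, 8-bit arithmetic.

as_int_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

#' Disc mean filter
#'
#' Replaces every pixel by the arithmetic mean over the disc of the given
#' radius (pixels whose center distance is <= radius), rounded to the
#' nearest integer; borders use edge replication. Volumes are filtered
#' slice-wise in the xy-plane (B-scan/C-scan raster images are 2D
#' entities; the axial direction is never mixed in).
#'
#' @param x 2D integer matrix, 3D `(z, y, x)` array, [oct_volume()] or
#'   [target_image()] (filtered per channel).
#' @param radius Disc radius in pixels (integer >= 0); 0 is the identity.
#' @return Same type and shape as the input.
#' @export
mean_filter <- function(x, radius = 2L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0 ||
      radius != floor(radius))
    stop("`radius` must be a single non-negative integer")
  radius <- as.integer(radius)
  if (inherits(x, "oct_volume")) {
    out <- x
    out$intensities <- mean_filter(x$intensities, radius)
    return(out)
  }
  if (inherits(x, "target_image")) {
    out <- x
    for (ch in 1:3)
      out$pixels[, , ch] <- .disc_mean_cpp(x$pixels[, , ch], radius)
    return(out)
  }
  if (is.matrix(x)) return(.disc_mean_cpp(as_int_matrix(x), radius))
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- x
    storage.mode(out) <- "integer"
    for (z in seq_len(dim(x)[1]))
      out[z, , ] <- .disc_mean_cpp(as_int_matrix(x[z, , ]), radius)
    return(out)
  }
  stop("`x` must be a matrix, 3D array, oct_volume or target_image")
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Rec. 601 luminance, `0.299 R + 0.587 G + 0.114 B`, rounded to the
#' nearest integer. The weights sum to 1, so neutral grays map to
#' themselves.
#'
#' @param img A [target_image()] or H x W x 3 array of 8-bit values.
#' @return 2D integer matrix of 8-bit values.
#' @export
to_grayscale8 <- function(img) {
  px <- if (inherits(img, "target_image")) img$pixels else img
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("`img` must have exactly 3 channels")
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  m <- matrix(as.integer(floor(g + 0.5)), dim(px)[1], dim(px)[2])
  m
}

#' Binarize an image or volume
#'
#' Values `>= threshold` become 255 (foreground), all others 0. With
#' `dark_target = TRUE` the complement of the image is thresholded instead
#' (`255 - x >= threshold`), so that dark-on-light objects — like the
#' printed red disc in the positioning workflow — become foreground.
#'
#' @param x 2D matrix, 3D array or [oct_volume()] of 8-bit values.
#' @param threshold 8-bit threshold in 0..255.
#' @param dark_target Threshold the complemented image (dark foreground).
#' @return Binary object of the same shape with values in \{0, 255\}.
#' @export
binarize <- function(x, threshold, dark_target = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255)
    stop("`threshold` must be a single value in [0, 255]")
  if (inherits(x, "oct_volume")) {
    out <- x
    out$intensities <- binarize(x$intensities, threshold, dark_target)
    return(out)
  }
  v <- if (dark_target) 255L - x else x
  out <- array(ifelse(v >= threshold, 255L, 0L), dim(x))
  storage.mode(out) <- "integer"
  out
}

is_binary <- function(x) {
  v <- if (inherits(x, "oct_volume")) x$intensities else x
  all(v == 0L | v == 255L)
}

# z index of the topmost foreground voxel per (y, x) column; 0 where empty.
# bin: (z, y, x) array with values {0, 255}
top_index <- function(bin) {
  d <- dim(bin)
  top <- matrix(0L, d[2], d[3])
  for (z in seq_len(d[1])) {
    sl <- bin[z, , , drop = TRUE]
    if (d[2] == 1L || d[3] == 1L) sl <- matrix(sl, d[2], d[3])
    top[sl != 0L] <- z
  }
  top
}

#' Three-class labeling of a binary biomass volume
#'
#' Splits a binarized C-scan into biofilm (150), voids within the structure
#' (50) and background (0). Under the default column-wise rule a zero voxel
#' is a void when it lies strictly below the topmost biomass voxel of its
#' own A-scan column ("under the roof"); everything above the roof, and
#' every column without biomass, is background. The stricter
#' `void_mode = "floodfill"` labels as void every zero voxel that cannot be
#' reached from the top slice through zero voxels by 6-connectivity, i.e.
#' only cavities fully enclosed in 3D.
#'
#' @param bin Binary [oct_volume()] or 3D `(z, y, x)` array with values in
#'   \{0, 255\}, substratum at z = 1.
#' @param void_mode `"column"` (default) or `"floodfill"`.
#' @return A `label_volume`: same shape, values in \{0, 50, 150\}, carrying
#'   the voxel spec when the input was an `oct_volume`.
#' @export
three_class_label <- function(bin, void_mode = c("column", "floodfill")) {
  void_mode <- match.arg(void_mode)
  voxel <- NULL
  meta <- NULL
  if (inherits(bin, "oct_volume")) {
    voxel <- bin$voxel
    meta <- bin[c("flow_cell", "day")]
    bin <- bin$intensities
  }
  if (!is.array(bin) || length(dim(bin)) != 3L)
    stop("`bin` must be a 3D (z, y, x) array")
  if (!is_binary(bin)) stop("input is not binary: values other than 0/255 found")
  d <- dim(bin)
  lab <- array(0L, d)
  lab[bin != 0L] <- 150L
  if (void_mode == "column") {
    top <- top_index(bin)
    for (z in seq_len(d[1])) {
      sl <- matrix(bin[z, , ], d[2], d[3])
      void_sl <- sl == 0L & top > z
      if (any(void_sl)) {
        lz <- matrix(lab[z, , ], d[2], d[3])
        lz[void_sl] <- 50L
        lab[z, , ] <- lz
      }
    }
  } else {
    reach <- floodfill_from_top(bin)
    lab[bin == 0L & !reach] <- 50L
  }
  structure(list(values = lab, voxel = voxel,
                 flow_cell = meta$flow_cell, day = meta$day),
            class = "label_volume")
}

# 6-connected reachability of zero voxels from the top (bulk) slice
floodfill_from_top <- function(bin) {
  d <- dim(bin)
  open <- bin == 0L
  reach <- array(FALSE, d)
  reach[d[1], , ] <- open[d[1], , ]
  repeat {
    grown <- reach
    # one dilation step along each of the six face directions
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[-1, , ]    <- grown[-1, , ]    | reach[-d[1], , ]
    if (d[2] > 1) {
      grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
      grown[, -1, ]    <- grown[, -1, ]    | reach[, -d[2], ]
    }
    if (d[3] > 1) {
      grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
      grown[, , -1]    <- grown[, , -1]    | reach[, , -d[3]]
    }
    grown <- grown & open
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- tabulate(match(x$values, c(0L, 50L, 150L)), 3L)
  cat(sprintf(
    "<label_volume> %s voxels: %d background, %d void, %d biofilm\n",
    paste(dim(x$values), collapse = " x "), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Maximum intensity projection
#'
#' Per-position maximum along the chosen axis. The default z-axis
#' projection of a C-scan yields the xy plan view from which substratum
#' coverage and textural entropy are computed.
#'
#' @param vol [oct_volume()] or 3D `(z, y, x)` array.
#' @param axis `"z"` (default, returns y x x), `"y"` (z x x) or
#'   `"x"` (z x y).
#' @return 2D integer matrix.
#' @export
max_intensity_projection <- function(vol, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  arr <- if (inherits(vol, "oct_volume")) vol$intensities else vol
  if (!is.array(arr) || length(dim(arr)) != 3L || length(arr) == 0L)
    stop("`vol` must be a non-empty 3D (z, y, x) array")
  ax <- switch(axis, z = 1L, y = 2L, x = 3L)
  a <- if (ax == 1L) arr else aperm(arr, c(ax, setdiff(1:3, ax)))
  d <- dim(a)
  m <- matrix(a[1, , ], d[2], d[3])
  for (k in seq_len(d[1])[-1]) m <- pmax(m, matrix(a[k, , ], d[2], d[3]))
  storage.mode(m) <- "integer"
  m
}
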