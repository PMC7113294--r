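# Structural biofilm parameters computed from binarized / labeled C-scans:
# substratum coverage, mean biofilm thickness, intrinsic and global
# porosity, height maps of the bulk-biofilm interface, and the
# co-occurrence textural entropy of projection images.

bin_array <- function(bin) {
  arr <- if (inherits(bin, "oct_volume")) bin$intensities else bin
  if (!is.array(arr) || length(dim(arr)) != 3L || length(arr) == 0L)
    stop("expected a non-empty 3D (z, y, x) array")
  if (!is_binary(arr)) stop("volume is not binary (values other than 0/255)")
  arr
}

#' Local biofilm thickness of one A-scan column
#'
#' The local thickness at a lateral position is the summed binary signal of
#' its A-scan divided by 255 (i.e. the biomass voxel count) times the
#' effective axial voxel height. Internal voids do not contribute: only
#' voxels set to 255 are counted.
#'
#' @param column Vector of binary values in \{0, 255\} along z.
#' @param dz Effective axial voxel height, µm (> 0).
#' @return Local thickness in µm.
#' @export
local_thickness <- function(column, dz) {
  if (!all(column %in% c(0, 255))) stop("column is not binary (0/255)")
  if (!is.numeric(dz) || length(dz) != 1L || dz <= 0)
    stop("`dz` must be a single positive number")
  sum(column) * dz / 255
}

#' Mean biofilm thickness of a binarized C-scan
#'
#' Arithmetic mean of the local thickness over all N A-scan columns of the
#' volume — biomass-free columns count as zero thickness. With
#' `mode = "interface"` the per-column biomass voxel count is replaced by
#' the height of the topmost biomass voxel, so voids below the interface
#' are included in the thickness.
#'
#' @param bin Binary [oct_volume()], or 3D `(z, y, x)` array plus `dz`.
#' @param dz Effective axial voxel height in µm; taken from the volume's
#'   voxel spec when `bin` is an `oct_volume`.
#' @param mode `"sum"` (default; biomass voxel count per column) or
#'   `"interface"` (topmost-interface height per column).
#' @return Mean thickness in µm.
#' @export
mean_biofilm_thickness <- function(bin, dz = NULL, mode = c("sum", "interface")) {
  mode <- match.arg(mode)
  if (inherits(bin, "oct_volume") && is.null(dz)) dz <- dz_eff(bin$voxel)
  if (is.null(dz)) stop("`dz` is required when `bin` is a bare array")
  arr <- bin_array(bin)
  d <- unname(dim(arr))
  n_cols <- d[2] * d[3]
  if (mode == "sum") {
    sum(as.numeric(arr)) / 255 * dz / n_cols
  } else {
    mean(top_index(arr)) * dz
  }
}

#' Substratum coverage from a maximum intensity projection
#'
#' Percentage of the projected substratum area overlain by biomass: every
#' pixel with value >= 1 in the z-direction MIP counts as biomass, pixels
#' equal to 0 as bare substratum.
#'
#' @param mip 2D 8-bit image (binary MIPs accepted).
#' @return Coverage in percent, 0..100.
#' @export
substratum_coverage <- function(mip) {
  if (is.null(dim(mip)) || length(mip) == 0L) stop("`mip` must be a non-empty 2D image")
  100 * sum(mip >= 1) / length(mip)
}

label_counts <- function(labels) {
  v <- if (inherits(labels, "label_volume")) labels$values else labels
  if (!all(v %in% c(0L, 50L, 150L)))
    stop("not a three-class label volume (values other than 0/50/150)")
  c(background = sum(v == 0L), void = sum(v == 50L), biofilm = sum(v == 150L))
}

#' Intrinsic biofilm porosity
#'
#' Void fraction within the biofilm envelope: the ratio of void voxels to
#' the sum of biofilm and void voxels, in percent, aggregated over all xz
#' longitudinal sections of the volume. Background voxels are excluded, so
#' the measure is independent of how much empty bulk lies above the
#' biofilm. Undefined (returns `NA`) when the volume holds no biomass and
#' no voids.
#'
#' @param labels A `label_volume` from [three_class_label()] (or a bare
#'   0/50/150 array).
#' @return Porosity in percent, or `NA` when undefined.
#' @export
intrinsic_porosity <- function(labels) {
  n <- label_counts(labels)
  denom <- n[["biofilm"]] + n[["void"]]
  if (denom == 0L) return(na_marker())
  100 * n[["void"]] / denom
}

#' Global biofilm porosity
#'
#' Fraction of non-biomass voxels beneath the bulk-biofilm interface, over
#' all voxels beneath it: per A-scan column every voxel from the substratum
#' up to the topmost biomass voxel is "beneath the interface"; the global
#' porosity is 100 x (beneath - biofilm voxels) / beneath. Unlike
#' [intrinsic_porosity()] this counts voids relative to the whole envelope
#' volume under the topography, not to the biomass-plus-void total.
#' Undefined (`NA`) for biomass-free volumes.
#'
#' Note that under the column void rule every sub-interface zero voxel is a
#' void, so the two porosities coincide there; they differ for volumes
#' labeled with `void_mode = "floodfill"`, where side-open spaces below the
#' interface count toward the global but not the intrinsic porosity.
#'
#' @inheritParams intrinsic_porosity
#' @return Porosity in percent, or `NA` when undefined.
#' @export
global_porosity <- function(labels) {
  v <- if (inherits(labels, "label_volume")) labels$values else labels
  if (!all(v %in% c(0L, 50L, 150L)))
    stop("not a three-class label volume (values other than 0/50/150)")
  bin <- array(ifelse(v == 150L, 255L, 0L), dim(v))
  below <- sum(as.numeric(top_index(bin)))      # voxels beneath the interface
  if (below == 0) return(na_marker())
  100 * (below - sum(v == 150L)) / below
}

#' Height map of the bulk-biofilm interface
#'
#' Per lateral position, the physical height of the topmost biomass voxel
#' (1-based z index times the effective axial voxel height); zero where the
#' column holds no biomass. This is the topographic representation used to
#' render biofilm surface maps.
#'
#' @param bin Binary [oct_volume()], or 3D array plus voxel spacings.
#' @param dz Effective axial voxel height, µm.
#' @param dx,dy Lateral spacing, µm (carried on the result for plotting).
#' @return Object of class `height_map`: list with `heights` (y x x matrix,
#'   µm), `dx`, `dy`.
#' @export
height_map <- function(bin, dz = NULL, dx = 1, dy = 1) {
  if (inherits(bin, "oct_volume")) {
    if (is.null(dz)) dz <- dz_eff(bin$voxel)
    dx <- bin$voxel$dx
    dy <- bin$voxel$dy
  }
  if (is.null(dz)) stop("`dz` is required when `bin` is a bare array")
  arr <- bin_array(bin)
  structure(list(heights = top_index(arr) * dz, dx = dx, dy = dy),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d positions, max height %.1f um\n",
              nrow(x$heights), ncol(x$heights), max(x$heights)))
  invisible(x)
}

#' Textural entropy of a projection image
#'
#' Shannon entropy (natural logarithm) of the gray-level co-occurrence
#' probability table of an image: all ordered pixel pairs separated by the
#' given offset are tallied into a 256 x 256 table of transitions a -> b,
#' normalized to probabilities p(a, b), and
#' TE = -sum p(a, b) ln p(a, b) over the nonzero entries. A perfectly
#' homogeneous image has a single transition and TE = 0; rough, patchy
#' interfaces raise TE. Optionally averaged over the four standard offsets
#' (0,1), (1,0), (1,1), (1,-1).
#'
#' @param mip 2D 8-bit image (typically the grayscale z-MIP of a filtered
#'   C-scan).
#' @param offset Integer pair `c(dy, dx)`, not both zero: pairs are
#'   `(img[y, x], img[y + dy, x + dx])`.
#' @param average4 Average TE over the four standard offsets.
#' @param levels Number of gray levels; 256 uses the 8-bit values as-is,
#'   smaller values bin the range 0..255 uniformly first.
#' @return Entropy in nats (>= 0).
#' @export
textural_entropy <- function(mip, offset = c(0L, 1L), average4 = FALSE,
                             levels = 256L) {
  if (is.null(dim(mip)) || length(dim(mip)) != 2L)
    stop("`mip` must be a 2D image")
  if (average4) {
    offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
    return(mean(vapply(offs, function(o)
      textural_entropy(mip, o, average4 = FALSE, levels = levels),
      numeric(1))))
  }
  if (length(offset) != 2L || all(offset == 0L))
    stop("`offset` must be a nonzero integer pair c(dy, dx)")
  m <- mip
  if (levels < 256L) m <- floor(m / 256 * levels) * (255 / (levels - 1))
  m <- round(m)
  H <- nrow(m); W <- ncol(m)
  dy <- as.integer(offset[1]); dx <- as.integer(offset[2])
  if (abs(dy) >= H || abs(dx) >= W)
    stop("image is smaller than the co-occurrence offset")
  ys <- seq_len(H - abs(dy))
  xs <- seq_len(W - abs(dx))
  if (length(ys) == 0L || length(xs) == 0L)
    stop("image is smaller than the co-occurrence offset")
  y0 <- if (dy >= 0) ys else ys + abs(dy)
  x0 <- if (dx >= 0) xs else xs + abs(dx)
  a <- m[y0, x0, drop = FALSE]
  b <- m[y0 + dy, x0 + dx, drop = FALSE]
  counts <- tabulate(as.integer(a) * 256L + as.integer(b) + 1L, 65536L)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) + 0  # + 0 normalizes IEEE negative zero
}

#' Full structural analysis of one OCT volume
#'
#' Orchestrates the standard workflow on a raw C-scan: optional crop to a
#' physical extent, slice-wise disc mean filter, binarization of the
#' biomass signal, three-class labeling, maximum intensity projection, and
#' all five structural parameters plus the height map. Undefined
#' parameters (porosities of a biomass-free channel) propagate as `NA`,
#' never as errors. Every parameter setting used is recorded on the result.
#'
#' @param vol A raw [oct_volume()].
#' @param crop_extent_mm Optional crop `c(x, y, z)` in mm before analysis.
#' @param filter_radius Disc mean-filter radius in px (default 2).
#' @param threshold Biomass binarization threshold on the filtered 8-bit
#'   data; the default 1 classifies every nonzero voxel as biomass.
#' @param void_mode Void rule for [three_class_label()].
#' @param te_offset,te_average4,te_levels Textural-entropy settings; TE is
#'   computed on the filtered grayscale MIP, not the binary one.
#' @param thickness_mode Passed to [mean_biofilm_thickness()].
#' @return A `structure_report`: one-row data.frame with columns
#'   `flow_cell`, `day`, `n_columns`, `sc_percent`, `mean_thickness_um`,
#'   `phi_intrinsic_percent`, `phi_global_percent`, `textural_entropy`,
#'   with the height map in `attr(, "height_map")` and the resolved
#'   parameters in `attr(, "params")`.
#' @export
structure_report <- function(vol, crop_extent_mm = NULL, filter_radius = 2L,
                             threshold = 1L,
                             void_mode = c("column", "floodfill"),
                             te_offset = c(0L, 1L), te_average4 = FALSE,
                             te_levels = 256L,
                             thickness_mode = c("sum", "interface")) {
  stopifnot(inherits(vol, "oct_volume"))
  void_mode <- match.arg(void_mode)
  thickness_mode <- match.arg(thickness_mode)
  if (!is.null(crop_extent_mm)) vol <- crop_volume(vol, crop_extent_mm)
  filt <- mean_filter(vol, filter_radius)
  gray_mip <- max_intensity_projection(filt, axis = "z")
  bin <- binarize(filt, threshold)
  labels <- three_class_label(bin, void_mode = void_mode)
  bin_mip <- max_intensity_projection(bin, axis = "z")
  hm <- height_map(bin)
  d <- unname(dim(vol$intensities))
  report <- data.frame(
    flow_cell = vol$flow_cell,
    day = vol$day,
    n_columns = d[2] * d[3],
    sc_percent = substratum_coverage(bin_mip),
    mean_thickness_um = mean_biofilm_thickness(bin, mode = thickness_mode),
    phi_intrinsic_percent = intrinsic_porosity(labels),
    phi_global_percent = global_porosity(labels),
    textural_entropy = textural_entropy(gray_mip, offset = te_offset,
                                        average4 = te_average4,
                                        levels = te_levels))
  attr(report, "height_map") <- hm
  attr(report, "params") <- list(
    crop_extent_mm = crop_extent_mm, filter_radius = filter_radius,
    threshold = threshold, void_mode = void_mode, te_offset = te_offset,
    te_average4 = te_average4, te_levels = te_levels,
    thickness_mode = thickness_mode,
    voxel = unclass(vol$voxel))
  class(report) <- c("structure_report", "data.frame")
  report
}
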