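# Data model for OCT C-scan volumes and 2D calibration-target images,
# TIFF/PNG readers and writers, and geometric/optical utilities.
#
# Coordinate convention, fixed package-wide: volumes are 3D arrays indexed
# (z, y, x) with z = 1 at the substratum plane and z increasing toward the
# bulk. All physical lengths are micrometres internally; millimetres appear
# only at the user/CLI boundary.

#' Voxel geometry of an OCT C-scan
#'
#' Describes the anisotropic voxel spacing of a volume. The axial spacing is
#' stored as measured in air; the effective axial spacing in the imaging
#' medium is derived as `dz_air / refractive_index` and never stored
#' independently, so the two can not drift apart.
#'
#' @param dx,dy Lateral voxel spacing in µm/voxel (x and y).
#' @param dz_air Axial voxel spacing in air, µm/voxel.
#' @param refractive_index Refractive index of the imaging medium
#'   (dimensionless, >= 1). Water is 1.33.
#' @return An object of class `voxel_spec`.
#' @examples
#' v <- voxel_spec(dx = 8, dy = 8, dz_air = 2.793, refractive_index = 1.33)
#' dz_eff(v)  # 2.1 µm
#' @export
voxel_spec <- function(dx, dy, dz_air, refractive_index = 1.33) {
  for (nm in c("dx", "dy", "dz_air")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("`", nm, "` must be a single positive number, got ", deparse(val))
  }
  if (!is.numeric(refractive_index) || length(refractive_index) != 1L ||
      !is.finite(refractive_index) || refractive_index < 1)
    stop("`refractive_index` must be a single number >= 1, got ",
         deparse(refractive_index))
  structure(
    list(dx = as.numeric(dx), dy = as.numeric(dy),
         dz_air = as.numeric(dz_air),
         refractive_index = as.numeric(refractive_index)),
    class = "voxel_spec")
}

#' @export
print.voxel_spec <- function(x, ...) {
  cat(sprintf(
    "<voxel_spec> dx=%g dy=%g dz_air=%g um/voxel, n=%g (effective dz=%g um)\n",
    x$dx, x$dy, x$dz_air, x$refractive_index, dz_eff(x)))
  invisible(x)
}

#' Effective axial voxel height in the imaging medium
#'
#' The axial sampling of an OCT device is specified in air; inside a medium
#' of refractive index n the optical path length is compressed, so the
#' effective axial voxel height is `dz_air / n`. All thickness and height
#' computations in this package use the effective value.
#'
#' @param dz_air Axial spacing in air, µm (> 0).
#' @param n Refractive index of the medium (>= 1).
#' @return Effective axial spacing in µm.
#' @examples
#' effective_axial_resolution(2.793, 1.33)  # 2.1
#' @export
effective_axial_resolution <- function(dz_air, n) {
  if (!is.numeric(dz_air) || length(dz_air) != 1L || !is.finite(dz_air) ||
      dz_air <= 0)
    stop("`dz_air` must be a single positive number")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a single number >= 1")
  dz_air / n
}

#' @rdname voxel_spec
#' @param voxel A `voxel_spec`.
#' @export
dz_eff <- function(voxel) {
  stopifnot(inherits(voxel, "voxel_spec"))
  effective_axial_resolution(voxel$dz_air, voxel$refractive_index)
}

#' Construct an OCT volume
#'
#' Wraps a 3D array of 8-bit intensities, indexed `(z, y, x)` with `z = 1`
#' at the substratum, together with its voxel geometry and acquisition
#' metadata (flow-cell id and cultivation day).
#'
#' @param intensities 3D numeric/integer array, values in 0..255, indexed
#'   `(z, y, x)`.
#' @param voxel A [voxel_spec()].
#' @param flow_cell Flow-cell id (integer, 1..32) or `NA`.
#' @param day Cultivation day (integer >= 0) or `NA`.
#' @param notes Free-text notes.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensities, voxel, flow_cell = NA_integer_,
                       day = NA_integer_, notes = "") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array indexed (z, y, x)")
  if (anyNA(intensities) || min(intensities) < 0 || max(intensities) > 255)
    stop("`intensities` must be 8-bit values in 0..255 without NA")
  stopifnot(inherits(voxel, "voxel_spec"))
  if (!is.na(day) && day < 0) stop("`day` must be >= 0")
  storage.mode(intensities) <- "integer"
  structure(
    list(intensities = intensities, voxel = voxel,
         flow_cell = as.integer(flow_cell), day = as.integer(day),
         notes = as.character(notes)),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  ext <- extent_mm(x)
  cat(sprintf(
    "<oct_volume> %d x %d x %d voxels (z,y,x), %.3f x %.3f x %.4f mm (x,y,z)\n",
    d[1], d[2], d[3], ext[1], ext[2], ext[3]))
  cat(sprintf("  flow cell %s, day %s\n",
              ifelse(is.na(x$flow_cell), "?", x$flow_cell),
              ifelse(is.na(x$day), "?", x$day)))
  invisible(x)
}

#' @rdname oct_volume
#' @param vol An `oct_volume`.
#' @return `extent_mm()`: physical extent in mm, named `c(x, y, z)`; the
#'   axial extent uses the effective (in-medium) voxel height.
#' @export
extent_mm <- function(vol) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensities)
  c(x = d[3] * vol$voxel$dx, y = d[2] * vol$voxel$dy,
    z = d[1] * dz_eff(vol$voxel)) / 1000
}

# rescale a >8-bit integer stack to 0..255 by min-max; constant input maps to 0
rescale_to_8bit <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(array(0L, dim(x)))
  array(as.integer(round((x - lo) / (hi - lo) * 255)), dim(x))
}

#' Load an OCT volume from a multi-page TIFF stack
#'
#' Reads a grayscale multi-page TIFF into an [oct_volume()]. Pages map to z
#' by default; set `page_axis = "y"` for stacks stored one B-scan (xz
#' cross-section) per page. OCT probes scan from the bulk downward, so page
#' order along z is reversed by default (`flip_z = TRUE`) to place the
#' substratum at `z = 1`.
#'
#' Voxel spacing is always supplied by the caller: vendor TIFF resolution
#' tags are unreliable and are only checked against the supplied spec — a
#' disagreement beyond 1% emits a warning, never an override. 16-bit input
#' is linearly min-max rescaled to 8-bit, since all thresholds in this
#' workflow are on the 8-bit scale.
#'
#' @param path Path to a multi-page TIFF file.
#' @param voxel A [voxel_spec()].
#' @param page_axis `"z"` (default; one xy slice per page) or `"y"` (one
#'   B-scan per page, rows = z, columns = x).
#' @param flip_z Reverse z order after assembly so z = 1 is the substratum.
#' @inheritParams oct_volume
#' @return An `oct_volume`.
#' @export
load_volume <- function(path, voxel, flow_cell = NA_integer_,
                        day = NA_integer_, notes = "",
                        page_axis = c("z", "y"), flip_z = TRUE) {
  page_axis <- match.arg(page_axis)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty TIFF stack: ", path)
  shapes <- vapply(pages, function(p) {
    d <- dim(p)
    if (length(d) != 2L)
      stop("page is not single-channel grayscale in ", path)
    d
  }, integer(2))
  ref <- shapes[, 1]
  bad <- which(shapes[1, ] != ref[1] | shapes[2, ] != ref[2])
  if (length(bad))
    stop("ragged TIFF stack: page ", bad[1], " is ",
         shapes[1, bad[1]], "x", shapes[2, bad[1]], " but page 1 is ",
         ref[1], "x", ref[2], " in ", path)
  maxval <- max(vapply(pages, max, numeric(1)))
  stack <- array(0L, dim = c(length(pages), ref[1], ref[2]))
  for (p in seq_along(pages)) stack[p, , ] <- pages[[p]]
  if (maxval > 255) {
    if (maxval > 65535)
      stop("unsupported bit depth (max value ", maxval, ") in ", path)
    stack <- rescale_to_8bit(stack)
  }
  check_resolution_tags(pages[[1]], voxel, path)
  # assemble into (z, y, x)
  if (page_axis == "z") {
    vol <- stack                       # (page=z, rows=y, cols=x)
  } else {
    vol <- aperm(stack, c(2, 1, 3))    # (rows=z, page=y, cols=x)
  }
  if (flip_z) vol <- vol[dim(vol)[1]:1, , , drop = FALSE]
  oct_volume(vol, voxel, flow_cell = flow_cell, day = day, notes = notes)
}

# warn when TIFF resolution tags disagree with the configured lateral spacing
# by more than 1%; tags are advisory only
check_resolution_tags <- function(page, voxel, path) {
  info <- attributes(page)
  xres <- info$x.resolution
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(invisible())
  unit <- if (!is.null(info$resolution.unit)) info$resolution.unit else "inch"
  um_per_unit <- switch(as.character(unit),
                        inch = 25400, cm = 10000, `2` = 25400, `3` = 10000,
                        NA_real_)
  if (is.na(um_per_unit)) return(invisible())
  implied_dx <- um_per_unit / xres
  if (abs(implied_dx - voxel$dx) / voxel$dx > 0.01)
    warning(sprintf(
      "TIFF resolution tag of %s implies dx = %.3f um but config says %.3f um; using config",
      path, implied_dx, voxel$dx))
  invisible()
}

#' Write an OCT volume to a multi-page TIFF stack
#'
#' Inverse of [load_volume()] with the same conventions (`page_axis`,
#' `flip_z`): `load_volume(write_volume(vol, p), vol$voxel)` reproduces the
#' voxel data exactly.
#'
#' @param vol An [oct_volume()].
#' @param path Output path.
#' @inheritParams load_volume
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, page_axis = c("z", "y"), flip_z = TRUE) {
  stopifnot(inherits(vol, "oct_volume"))
  page_axis <- match.arg(page_axis)
  arr <- vol$intensities
  if (flip_z) arr <- arr[dim(arr)[1]:1, , , drop = FALSE]
  if (page_axis == "y") arr <- aperm(arr, c(2, 1, 3))
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(p) arr[p, , , drop = TRUE] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Crop an OCT volume to a physical extent
#'
#' Shapes are derived by the floor rule `floor(extent_um / spacing)` per
#' axis (axial spacing is the effective in-medium value), so a request of
#' 7 x 5 x 0.45 mm on an 8 x 8 x 2.1 µm grid yields 875 x 625 x 214 voxels.
#' The voxel spec is unchanged; physical extent stays consistent with shape
#' after the crop.
#'
#' @param vol An [oct_volume()].
#' @param extent_mm Requested extent in mm, `c(x, y, z)`.
#' @param origin Voxel offsets `c(x, y, z)` (0-based) of the crop origin.
#' @return The cropped `oct_volume`.
#' @export
crop_volume <- function(vol, extent_mm, origin = c(0L, 0L, 0L)) {
  stopifnot(inherits(vol, "oct_volume"), length(extent_mm) == 3L,
            length(origin) == 3L)
  if (any(extent_mm <= 0)) stop("`extent_mm` must be positive")
  if (any(origin < 0)) stop("`origin` offsets must be >= 0")
  d <- dim(vol$intensities)                     # (z, y, x)
  sp <- c(vol$voxel$dx, vol$voxel$dy, dz_eff(vol$voxel))  # (x, y, z)
  want <- floor(extent_mm * 1000 / sp)          # voxels per (x, y, z)
  avail <- c(d[3], d[2], d[1]) - origin
  ax_names <- c("x", "y", "z")
  for (k in 1:3) {
    if (want[k] > avail[k])
      stop(sprintf(
        "crop extent exceeds volume on %s-axis: requested %d voxels (%.3f mm) but only %d available from origin",
        ax_names[k], want[k], extent_mm[k], avail[k]))
    if (want[k] < 1)
      stop("crop extent smaller than one voxel on ", ax_names[k], "-axis")
  }
  sub <- vol$intensities[origin[3] + seq_len(want[3]),
                         origin[2] + seq_len(want[2]),
                         origin[1] + seq_len(want[1]), drop = FALSE]
  oct_volume(sub, vol$voxel, flow_cell = vol$flow_cell, day = vol$day,
             notes = vol$notes)
}

#' Volumetric flow rate of a rectangular flow channel
#'
#' Converts a mean flow velocity and channel cross-section to the
#' volumetric flow rate, for reporting flow-cell operating conditions:
#' `Q = u * width * height * 60 / 1000` (mm³/s to mL/min).
#'
#' @param u Mean flow velocity, mm/s.
#' @param width,height Channel cross-section, mm.
#' @return Flow rate in mL/min.
#' @examples
#' flow_rate(6, 5, 0.45)  # 0.81 mL/min
#' @export
flow_rate <- function(u, width, height) {
  if (any(c(u, width, height) <= 0) || any(!is.finite(c(u, width, height))))
    stop("all arguments must be positive finite numbers")
  u * width * height * 60 / 1000
}

#' Construct a calibration-target image
#'
#' A 2D RGB 8-bit image of the printed positioning target, with physical
#' pixel sizes derived from the microscope field of view divided by the
#' pixel count.
#'
#' @param pixels H x W x 3 array of 8-bit values.
#' @param px_size_x,px_size_y Pixel size in µm/pixel (> 0).
#' @return An object of class `target_image`.
#' @export
target_image <- function(pixels, px_size_x, px_size_y) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 RGB array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("`pixels` must be 8-bit values in 0..255")
  if (px_size_x <= 0 || px_size_y <= 0) stop("pixel sizes must be > 0")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, px_size_x = as.numeric(px_size_x),
                 px_size_y = as.numeric(px_size_y)),
            class = "target_image")
}

#' @export
print.target_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<target_image> %d x %d px, %.4f x %.4f um/px\n",
              d[2], d[1], x$px_size_x, x$px_size_y))
  invisible(x)
}

#' Read and write calibration-target images
#'
#' PNG or single-page RGB TIFF. Pixel sizes are derived from the stated
#' field of view divided by the image pixel count.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @param fov_mm Field of view `c(x, y)` in mm; default is the 6.7 x 5.0 mm
#'   field of the USB microscope used for positioning tests.
#' @return A [target_image()].
#' @export
load_target_image <- function(path, fov_mm = c(6.7, 5.0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path) * 255,
                tif = ,
                tiff = tiff::readTIFF(path, as.is = TRUE),
                stop("unsupported image format: .", ext))
  if (length(dim(raw)) == 2L)
    raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  px <- array(as.integer(round(raw)), dim = dim(raw))
  d <- dim(px)
  target_image(px, px_size_x = fov_mm[1] * 1000 / d[2],
               px_size_y = fov_mm[2] * 1000 / d[1])
}

#' @rdname load_target_image
#' @param img A [target_image()].
#' @export
write_target_image <- function(img, path) {
  stopifnot(inherits(img, "target_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Read a voxel spec from a JSON sidecar file
#'
#' Sidecar format: a JSON object with fields `dx`, `dy`, `dz_air` and
#' `refractive_index` (all µm except the dimensionless index).
#'
#' @param path Path to the JSON file.
#' @return A [voxel_spec()].
#' @export
read_voxel_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("dx", "dy", "dz_air"))
    if (is.null(x[[f]])) stop("voxel sidecar ", path, " is missing `", f, "`")
  voxel_spec(x$dx, x$dy, x$dz_air,
             refractive_index = if (is.null(x$refractive_index)) 1.33
                                else x$refractive_index)
}
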