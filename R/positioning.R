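# Detection of the printed calibration target in microscope images and the
# positioning-accuracy statistics computed from repeated detections:
# center-of-mass deviations from the series mean, quartile summaries,
# 1.5*IQR outlier flags, and the tolerance report against the optical
# resolution of the scanner.

#' Detect the calibration target and compute its center of mass
#'
#' Runs the target-detection pipeline on one microscope image: disc mean
#' filter (radius 2 px), conversion to 8-bit grayscale, binarization at the
#' given threshold with dark-object polarity (the printed disc is darker
#' than the paper), connected-component analysis with 8-connectivity, and
#' a particle-size gate that discards artifacts such as dust specks. Among
#' the surviving components the largest is taken and its unweighted
#' centroid — for a disc, the midpoint — is returned in physical units.
#'
#' Pixel coordinates are 0-based, so a disc centered on pixel (800, 600)
#' yields a center of mass of (800 px_size_x, 600 px_size_y) µm.
#'
#' @param img A [target_image()].
#' @param threshold 8-bit binarization threshold (default 120).
#' @param min_area_px,max_area_px Particle-size gate in pixels; defaults
#'   are 25% and 400% of the nominal disc area
#'   pi (d/2)^2 / (px_size_x px_size_y) for `target_diameter_mm`.
#' @param filter_radius Mean-filter radius in px (default 2).
#' @param channel Gray conversion: `"luminance"` (default), or a single
#'   color channel (`"red"` makes the red disc nearly invisible; `"green"`
#'   maximizes its contrast).
#' @param target_diameter_mm Nominal printed disc diameter (default 1 mm).
#' @param image_id Identifier carried into the result.
#' @return A `com_record`: one-row data.frame with `image_id`, `x_com_um`,
#'   `y_com_um`, `area_px`.
#' @export
detect_target <- function(img, threshold = 120L, min_area_px = NULL,
                          max_area_px = NULL, filter_radius = 2L,
                          channel = c("luminance", "red", "green"),
                          target_diameter_mm = 1,
                          image_id = NA_character_) {
  stopifnot(inherits(img, "target_image"))
  channel <- match.arg(channel)
  nominal <- pi * (target_diameter_mm * 1000 / 2)^2 /
    (img$px_size_x * img$px_size_y)
  if (is.null(min_area_px)) min_area_px <- 0.25 * nominal
  if (is.null(max_area_px)) max_area_px <- 4 * nominal

  filt <- mean_filter(img, filter_radius)
  gray <- switch(channel,
                 luminance = to_grayscale8(filt),
                 red = filt$pixels[, , 1],
                 green = filt$pixels[, , 2])
  storage.mode(gray) <- "integer"
  mask <- binarize(gray, threshold, dark_target = TRUE)
  lab <- .label_components8_cpp(mask)
  n_comp <- max(lab)
  if (n_comp == 0L) stop("target not found: no foreground components")
  areas <- tabulate(lab[lab > 0L], n_comp)
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  if (length(keep) == 0L)
    stop("target not found: no component within the size gate [",
         round(min_area_px), ", ", round(max_area_px), "] px")
  best <- keep[which.max(areas[keep])]
  if (sum(areas[keep] >= 0.9 * areas[best]) > 1L)
    warning("ambiguous target: multiple components of comparable size; ",
            "using the largest")
  idx <- which(lab == best, arr.ind = TRUE)
  # unweighted centroid in 0-based pixel coordinates, scaled to um
  data.frame(image_id = image_id,
             x_com_um = (mean(idx[, 2]) - 1) * img$px_size_x,
             y_com_um = (mean(idx[, 1]) - 1) * img$px_size_y,
             area_px = areas[best])
}

axis_summary <- function(dev) {
  q <- unname(quantile(dev, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  list(mean = mean(dev), median = median(dev), sd = sd(dev),
       q1 = q[1], q3 = q[2], iqr = iqr,
       fence_lower = lower, fence_upper = upper,
       min = min(dev), max = max(dev),
       outlier = dev < lower | dev > upper)
}

#' Center-of-mass deviations of a positioning series
#'
#' For a series of repeated target detections, the deviation of each
#' measurement from the series mean is computed per axis:
#' `dx_i = x_i - mean(x)` and `dy_i = y_i - mean(y)`. By construction the
#' deviations sum to zero on each axis; their spread quantifies the
#' positioning accuracy of the stage. Observations outside
#' `\[Q1 - 1.5 IQR, Q3 + 1.5 IQR\]` (quartiles by linear interpolation) are
#' flagged as outliers per axis.
#'
#' @param records data.frame with columns `x_com_um`, `y_com_um` (e.g.
#'   rbind-ed [detect_target()] results), >= 2 rows.
#' @return A `deviation_set`: data.frame with per-record `dx_um`, `dy_um`,
#'   `outlier_x`, `outlier_y`, plus a `summary` attribute (per-axis mean,
#'   median, sd, quartiles, IQR, fences, min, max, n_outliers).
#' @export
com_deviations <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("x_com_um", "y_com_um") %in% names(records)))
    stop("`records` must be a data.frame with x_com_um and y_com_um")
  if (nrow(records) < 2L) stop("need at least 2 records")
  dx <- records$x_com_um - mean(records$x_com_um)
  dy <- records$y_com_um - mean(records$y_com_um)
  sx <- axis_summary(dx)
  sy <- axis_summary(dy)
  out <- data.frame(
    image_id = if ("image_id" %in% names(records)) records$image_id
               else seq_len(nrow(records)),
    dx_um = dx, dy_um = dy,
    outlier_x = sx$outlier, outlier_y = sy$outlier)
  summarize_axis <- function(s, n_out) {
    data.frame(mean = s$mean, median = s$median, sd = s$sd, q1 = s$q1,
               q3 = s$q3, iqr = s$iqr, fence_lower = s$fence_lower,
               fence_upper = s$fence_upper, min = s$min, max = s$max,
               n_outliers = n_out)
  }
  summ <- rbind(x = summarize_axis(sx, sum(sx$outlier)),
                y = summarize_axis(sy, sum(sy$outlier)))
  summ <- cbind(axis = c("x", "y"), summ)
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  class(out) <- c("deviation_set", "data.frame")
  out
}

#' Positioning-accuracy report against a tolerance
#'
#' Evaluates a deviation series against the accuracy required for reliable
#' structural imaging: the positioning error must not exceed the lateral
#' optical resolution of the tomograph (8 µm for the system this workflow
#' was designed around), otherwise repeated scans of the same flow cell are
#' not comparable voxel-by-voxel. Reports, per axis, the fraction of
#' deviations within the tolerance and the IQR half-width; the series
#' passes when at least 75% of movements are within tolerance on both
#' axes.
#'
#' @param dev A [com_deviations()] result.
#' @param tolerance_um Accuracy tolerance in µm (default 8, the lateral
#'   optical resolution).
#' @return An `accuracy_report`: list with `tolerance_um`, per-axis
#'   `fraction_within`, `iqr_half_width_um`, `n`, and logical `pass`.
#' @export
accuracy_report <- function(dev, tolerance_um = 8) {
  stopifnot(inherits(dev, "deviation_set"))
  if (nrow(dev) == 0L) stop("empty deviation set")
  summ <- attr(dev, "summary")
  frac <- c(x = mean(abs(dev$dx_um) <= tolerance_um),
            y = mean(abs(dev$dy_um) <= tolerance_um))
  half <- c(x = summ$iqr[summ$axis == "x"] / 2,
            y = summ$iqr[summ$axis == "y"] / 2)
  structure(list(tolerance_um = tolerance_um, n = nrow(dev),
                 fraction_within = frac, iqr_half_width_um = half,
                 pass = all(frac >= 0.75)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> n = %d, tolerance = %g um\n", x$n,
              x$tolerance_um))
  cat(sprintf("  fraction within tolerance: x %.3f, y %.3f\n",
              x$fraction_within[["x"]], x$fraction_within[["y"]]))
  cat(sprintf("  IQR half-width: x %.2f um, y %.2f um\n",
              x$iqr_half_width_um[["x"]], x$iqr_half_width_um[["y"]]))
  cat(sprintf("  %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
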