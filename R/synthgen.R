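# Synthetic-data generator standing in for the instrument: biofilm growth
# phantoms with exactly known ground truth (by direct voxel counting on the
# noise-free mask, never via the analysis pipeline), and calibration-target
# images with known sub-pixel centers. Everything is deterministic given
# the seed.

#' Growth parameters for the synthetic biofilm series
#'
#' Defaults emulate the cultivation this workflow was designed to monitor:
#' a 450 µm-high flow channel imaged at 8 x 8 µm lateral / 2.1 µm
#' effective axial voxel pitch over a 7 x 5 mm field, colonies appearing
#' at about 1 per mm² per day and growing 100 µm/day laterally and
#' 35 µm/day vertically — reaching near-full substratum coverage and a
#' mean thickness approaching 200 µm within six days. Tests and examples
#' typically pass a coarser voxel grid and a smaller field to keep volumes
#' small.
#'
#' @param seeding_rate_mm2_day Expected new colonies per mm² per day.
#' @param lateral_rate_um_day Lateral radius growth, µm/day.
#' @param vertical_rate_um_day Vertical (height) growth, µm/day.
#' @param void_fraction Fraction of colony voxels carved out as internal
#'   voids, in \[0, 1).
#' @param noise_sd Additive Gaussian noise level on the 8-bit scale
#'   (clipped to \[0, 255\]); 0 disables noise.
#' @param channel_height_um Flow-channel height (clips vertical growth).
#' @param extent_x_mm,extent_y_mm Lateral extent of the simulated field.
#' @param voxel A [voxel_spec()].
#' @param biomass_intensity 8-bit intensity of biomass voxels.
#' @param seed Random seed (determinism contract: same seed, same series).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(seeding_rate_mm2_day = 1,
                          lateral_rate_um_day = 100,
                          vertical_rate_um_day = 35,
                          void_fraction = 0.15,
                          noise_sd = 8,
                          channel_height_um = 450,
                          extent_x_mm = 7, extent_y_mm = 5,
                          voxel = voxel_spec(8, 8, 2.793, 1.33),
                          biomass_intensity = 180L,
                          seed = 1L) {
  stopifnot(inherits(voxel, "voxel_spec"))
  if (seeding_rate_mm2_day < 0 || lateral_rate_um_day < 0 ||
      vertical_rate_um_day < 0 || noise_sd < 0)
    stop("rates and noise level must be >= 0")
  if (void_fraction < 0 || void_fraction >= 1)
    stop("`void_fraction` must be in [0, 1)")
  if (channel_height_um < dz_eff(voxel))
    stop("channel height is smaller than one axial voxel")
  structure(list(seeding_rate_mm2_day = seeding_rate_mm2_day,
                 lateral_rate_um_day = lateral_rate_um_day,
                 vertical_rate_um_day = vertical_rate_um_day,
                 void_fraction = void_fraction, noise_sd = noise_sd,
                 channel_height_um = channel_height_um,
                 extent_x_mm = extent_x_mm, extent_y_mm = extent_y_mm,
                 voxel = voxel,
                 biomass_intensity = as.integer(biomass_intensity),
                 seed = as.integer(seed)),
            class = "growth_params")
}

# voxelize hemi-ellipsoidal colonies (spherical caps stretched to the
# lateral/vertical growth ratio) into a logical (z, y, x) mask
voxelize_colonies <- function(centers_um, rl_um, rv_um, d, sp) {
  mask <- array(FALSE, d)
  if (nrow(centers_um) == 0L) return(mask)
  xs <- (seq_len(d[3]) - 0.5) * sp["dx"]   # voxel centers, um
  ys <- (seq_len(d[2]) - 0.5) * sp["dy"]
  zs <- (seq_len(d[1]) - 0.5) * sp["dz"]
  for (k in seq_len(nrow(centers_um))) {
    if (rl_um[k] <= 0 || rv_um[k] <= 0) next
    xi <- which(abs(xs - centers_um[k, 1]) <= rl_um[k])
    yi <- which(abs(ys - centers_um[k, 2]) <= rl_um[k])
    zi <- which(zs <= rv_um[k])
    if (!length(xi) || !length(yi) || !length(zi)) next
    ex <- ((xs[xi] - centers_um[k, 1]) / rl_um[k])^2
    ey <- ((ys[yi] - centers_um[k, 2]) / rl_um[k])^2
    ez <- (zs[zi] / rv_um[k])^2
    # inside: ex + ey + ez <= 1
    lat <- outer(ey, ex, "+")                       # (y, x)
    for (iz in seq_along(zi)) {
      inside <- lat <= 1 - ez[iz]
      if (any(inside)) {
        sl <- mask[zi[iz], yi, xi]
        mask[zi[iz], yi, xi] <- sl | inside
      }
    }
  }
  mask
}

# carve ellipsoidal voids into the biomass mask until `target` voxels are
# removed; never removes the topmost biomass voxel of any column, so the
# interface topography (and hence coverage and ground truth) is untouched
carve_voids <- function(mask, target, sp) {
  if (target <= 0) return(list(mask = mask, carved = 0L))
  d <- dim(mask)
  top <- top_index(array(ifelse(mask, 255L, 0L), d))
  zidx <- slice.index(mask, 1)
  topfull <- array(rep(top, each = d[1]), d)
  eligible <- mask & zidx < topfull
  carved_total <- 0L
  guard <- 0L
  cand_all <- which(eligible)  # eligibility only shrinks; stale hits skipped
  if (length(cand_all) == 0L) return(list(mask = mask, carved = 0L))
  while (carved_total < target && guard < 50000L) {
    guard <- guard + 1L
    c0 <- cand_all[sample.int(length(cand_all), 1L)]
    if (!eligible[c0]) next
    ijk <- arrayInd(c0, d)  # (z, y, x)
    rz <- sample(2:4, 1L)
    ry <- sample(2:4, 1L)
    rx <- sample(2:4, 1L)
    zi <- max(1, ijk[1] - rz):min(d[1], ijk[1] + rz)
    yi <- max(1, ijk[2] - ry):min(d[2], ijk[2] + ry)
    xi <- max(1, ijk[3] - rx):min(d[3], ijk[3] + rx)
    ez <- ((zi - ijk[1]) / rz)^2
    ey <- ((yi - ijk[2]) / ry)^2
    ex <- ((xi - ijk[3]) / rx)^2
    ell <- outer(ez, outer(ey, ex, "+"), "+") <= 1  # (z, y, x) block
    block_el <- eligible[zi, yi, xi, drop = FALSE]
    rm <- ell & array(block_el, dim(ell))
    n_rm <- sum(rm)
    if (n_rm == 0L) next
    if (carved_total + n_rm > target) {
      # trim the excess deterministically to land exactly on target
      keep_n <- target - carved_total
      idx_rm <- which(rm)
      rm[] <- FALSE
      rm[idx_rm[seq_len(keep_n)]] <- TRUE
      n_rm <- keep_n
    }
    sub_mask <- mask[zi, yi, xi, drop = FALSE]
    sub_mask[rm] <- FALSE
    mask[zi, yi, xi] <- sub_mask
    sub_el <- eligible[zi, yi, xi, drop = FALSE]
    sub_el[rm] <- FALSE
    eligible[zi, yi, xi] <- sub_el
    carved_total <- carved_total + n_rm
  }
  list(mask = mask, carved = carved_total)
}

#' Simulate a biofilm growth series with known ground truth
#'
#' Grows hemi-ellipsoidal colonies on the substratum of a flow channel:
#' each day new colonies appear (Poisson seeding), existing ones expand at
#' the lateral/vertical rates, merging colonies union their masks, growth
#' clips at the channel height. Internal voids are carved as small
#' ellipsoids (never touching a column's interface voxel) until the
#' requested fraction of colony voxels is removed. The returned volume is
#' the voxelized phantom at the biomass intensity plus clipped additive
#' Gaussian noise; the ground truth (coverage, mean thickness, void
#' fraction) is computed by direct voxel counting on the noise-free mask.
#'
#' @param params A [growth_params()].
#' @param days Number of days to simulate (volumes for days 1..days).
#' @return List of length `days`; each element has `volume` (an
#'   [oct_volume()]) and `truth` (list: `day`, `sc_percent`,
#'   `mean_thickness_um`, `void_fraction_percent`, `n_biomass_voxels`,
#'   `n_void_voxels`).
#' @export
synth_biofilm_series <- function(params, days) {
  stopifnot(inherits(params, "growth_params"), days >= 1)
  v <- params$voxel
  dz <- dz_eff(v)
  d <- unname(c(floor(params$channel_height_um / dz),      # z
                floor(params$extent_y_mm * 1000 / v$dy),   # y
                floor(params$extent_x_mm * 1000 / v$dx)))  # x
  if (d[1] < 1) stop("channel height is smaller than one axial voxel")
  sp <- c(dx = v$dx, dy = v$dy, dz = dz)
  area_mm2 <- params$extent_x_mm * params$extent_y_mm
  set.seed(params$seed)
  # seed colonies for every day up front so the series is a growing nest
  seeded <- lapply(seq_len(days), function(day) {
    n_new <- rpois(1, params$seeding_rate_mm2_day * area_mm2)
    cbind(x = runif(n_new, 0, params$extent_x_mm * 1000),
          y = runif(n_new, 0, params$extent_y_mm * 1000))
  })
  out <- vector("list", days)
  for (day in seq_len(days)) {
    centers <- do.call(rbind, seeded[seq_len(day)])
    ages <- rep(seq(day, 1), vapply(seeded[seq_len(day)], nrow, integer(1)))
    rl <- ages * params$lateral_rate_um_day
    rv <- pmin(ages * params$vertical_rate_um_day, params$channel_height_um)
    mask <- voxelize_colonies(centers, rl, rv, d, sp)
    n_solid <- sum(mask)
    carve_target <- round(params$void_fraction * n_solid)
    cv <- carve_voids(mask, carve_target, sp)
    mask <- cv$mask
    n_biofilm <- n_solid - cv$carved
    # ground truth by direct voxel counting on the noise-free mask
    top <- top_index(array(ifelse(mask, 255L, 0L), d))
    truth <- list(
      day = day,
      sc_percent = unname(100 * sum(top > 0L) / (d[2] * d[3])),
      mean_thickness_um = unname(n_biofilm * dz / (d[2] * d[3])),
      void_fraction_percent =
        if (n_biofilm + cv$carved == 0L) NA_real_
        else 100 * cv$carved / (n_biofilm + cv$carved),
      n_biomass_voxels = n_biofilm,
      n_void_voxels = cv$carved)
    img <- array(0, d)
    img[mask] <- params$biomass_intensity
    if (params$noise_sd > 0)
      img <- img + rnorm(length(img), 0, params$noise_sd)
    img <- array(pmin(pmax(round(img), 0L), 255L), d)
    out[[day]] <- list(
      volume = oct_volume(img, v, day = day),
      truth = truth)
  }
  out
}

#' Render a synthetic calibration-target image
#'
#' Draws an anti-aliased red disc of the printed-target geometry (default
#' 1 mm diameter) on a light paper-like background at the microscope's
#' native resolution (1600 x 1200 px, 6.7 x 5.0 mm field of view), with
#' the disc center displaced from the image center by a known sub-pixel
#' offset. Optional dust specks (small dark blobs) are placed away from
#' the disc, emulating artifacts the particle filter must reject.
#'
#' @param offset_um Disc-center offset from the image center, `c(x, y)` µm.
#' @param dust Number of dust specks.
#' @param seed Random seed.
#' @param width_px,height_px Image size in pixels.
#' @param fov_mm Field of view `c(x, y)` in mm.
#' @param diameter_mm Disc diameter in mm.
#' @param noise_sd Per-channel Gaussian pixel noise (8-bit counts).
#' @return List with `image` (a [target_image()]) and `true_center_um`
#'   (named `c(x, y)`: the disc center in the 0-based-pixel µm frame used
#'   by [detect_target()]).
#' @export
synth_target_image <- function(offset_um = c(0, 0), dust = 0L, seed = 1L,
                               width_px = 1600L, height_px = 1200L,
                               fov_mm = c(6.7, 5.0), diameter_mm = 1,
                               noise_sd = 2) {
  px_x <- fov_mm[1] * 1000 / width_px
  px_y <- fov_mm[2] * 1000 / height_px
  r_um <- diameter_mm * 1000 / 2
  cx_um <- (width_px - 1) / 2 * px_x + offset_um[1]
  cy_um <- (height_px - 1) / 2 * px_y + offset_um[2]
  if (cx_um - r_um < 0 || cx_um + r_um > (width_px - 1) * px_x ||
      cy_um - r_um < 0 || cy_um + r_um > (height_px - 1) * px_y)
    stop("disc is not fully inside the image")
  set.seed(seed)
  xs <- (seq_len(width_px) - 1) * px_x
  ys <- (seq_len(height_px) - 1) * px_y
  dist <- sqrt(outer((ys - cy_um)^2, (xs - cx_um)^2, "+"))
  aa <- mean(c(px_x, px_y))  # anti-aliasing ramp width ~ one pixel
  alpha <- pmin(pmax((r_um + aa / 2 - dist) / aa, 0), 1)
  bg <- c(245, 245, 245)
  fg <- c(200, 30, 30)  # printed red
  px <- array(0, c(height_px, width_px, 3))
  for (ch in 1:3)
    px[, , ch] <- bg[ch] + (fg[ch] - bg[ch]) * alpha
  if (dust > 0) {
    placed <- 0L
    guard <- 0L
    while (placed < dust && guard < 100L * dust) {
      guard <- guard + 1L
      dx_um <- runif(1, 0, (width_px - 1) * px_x)
      dy_um <- runif(1, 0, (height_px - 1) * px_y)
      sr_um <- runif(1, 10, 40)  # speck radius 10-40 um
      # keep specks clear of the disc so they stay separate components
      if (sqrt((dx_um - cx_um)^2 + (dy_um - cy_um)^2) < r_um + 3 * sr_um + 30)
        next
      sd2 <- sqrt(outer((ys - dy_um)^2, (xs - dx_um)^2, "+"))
      sa <- pmin(pmax((sr_um + aa / 2 - sd2) / aa, 0), 1)
      shade <- runif(1, 20, 80)
      for (ch in 1:3)
        px[, , ch] <- px[, , ch] * (1 - sa) + shade * sa
      placed <- placed + 1L
    }
  }
  if (noise_sd > 0)
    px <- px + rnorm(length(px), 0, noise_sd)
  px <- array(as.integer(pmin(pmax(round(px), 0L), 255L)), dim(px))
  list(image = target_image(px, px_x, px_y),
       true_center_um = c(x = cx_um, y = cy_um))
}
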