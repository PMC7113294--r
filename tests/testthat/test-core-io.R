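test_that("voxel spec validates inputs and derives the effective dz", {
  v <- voxel_spec(8, 8, 2.793, 1.33)
  expect_equal(dz_eff(v), 2.793 / 1.33)
  expect_error(voxel_spec(0, 8, 2), "dx")
  expect_error(voxel_spec(8, 8, -1), "dz_air")
  expect_error(voxel_spec(8, 8, 2, 0.9), "refractive_index")
})

test_that("effective axial resolution follows the refractive-index correction", {
  expect_equal(effective_axial_resolution(2.1, 1.0), 2.1)
  expect_equal(effective_axial_resolution(2.793, 1.33), 2.1, tolerance = 0.01 / 2.1)
  expect_equal(effective_axial_resolution(4.2, 1.33), 3.158, tolerance = 0.001 / 3.158)
  expect_error(effective_axial_resolution(-1, 1.33))
  expect_error(effective_axial_resolution(2.1, 0.99))
  # strictly decreasing in n, linear in dz_air
  ns <- seq(1, 2, by = 0.1)
  vals <- vapply(ns, function(n) effective_axial_resolution(3, n), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(effective_axial_resolution(6, 1.2),
               3 * effective_axial_resolution(2, 1.2))
})

test_that("flow rate reproduces the operating point and is linear in each argument", {
  expect_equal(flow_rate(6, 5, 0.45), 0.81)
  expect_equal(flow_rate(1, 1, 1), 0.06)
  expect_equal(flow_rate(12, 5, 0.45), 1.62)
  expect_equal(flow_rate(6, 10, 0.45), 2 * flow_rate(6, 5, 0.45))
  expect_equal(flow_rate(6, 5, 0.9), 2 * flow_rate(6, 5, 0.45))
  expect_error(flow_rate(0, 5, 0.45))
})

test_that("TIFF stack round-trips preserve pixel content exactly", {
  withr::local_seed(7)
  path <- withr::local_tempfile(fileext = ".tif")
  arr <- array(sample(0:255, 10 * 16 * 12, TRUE), c(10, 16, 12))
  vol <- oct_volume(arr, vx())
  write_volume(vol, path)
  back <- load_volume(path, vx())
  expect_identical(back$intensities, vol$intensities)
  # all-zero identity case
  write_volume(oct_volume(array(0L, c(10, 64, 64)),
                          voxel_spec(8, 8, 2.793, 1.33)), path)
  z <- load_volume(path, voxel_spec(8, 8, 2.793, 1.33))
  expect_identical(dim(z$intensities), c(10L, 64L, 64L))
  expect_true(all(z$intensities == 0L))
})

test_that("B-scan-per-page stacks and flip_z assemble into the (z, y, x) convention", {
  path <- withr::local_tempfile(fileext = ".tif")
  withr::local_seed(8)
  arr <- array(sample(0:255, 6 * 5 * 4, TRUE), c(6, 5, 4))  # (z, y, x)
  vol <- oct_volume(arr, vx())
  write_volume(vol, path, page_axis = "y", flip_z = FALSE)
  back <- load_volume(path, vx(), page_axis = "y", flip_z = FALSE)
  expect_identical(back$intensities, arr)
  # flip_z on both sides is also an identity
  write_volume(vol, path, flip_z = TRUE)
  expect_identical(load_volume(path, vx(), flip_z = TRUE)$intensities, arr)
  # flip_z only on read reverses z
  write_volume(vol, path, flip_z = FALSE)
  rev_back <- load_volume(path, vx(), flip_z = TRUE)
  expect_identical(rev_back$intensities, arr[6:1, , ])
})

test_that("ragged stacks and missing files raise explicit errors", {
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(0, 64, 64), matrix(0, 32, 32), matrix(0, 64, 64))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  expect_error(load_volume(path, vx()), "ragged.*page 2")
  expect_error(load_volume("/nonexistent/vol.tif", vx()), "not found")
})

test_that("16-bit stacks are min-max rescaled to the 8-bit range", {
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(c(0, 65535, 32768, 0), 2, 2) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  vol <- load_volume(path, vx(), flip_z = FALSE)
  expect_equal(max(vol$intensities), 255L)
  expect_equal(min(vol$intensities), 0L)
  expect_equal(vol$intensities[1, 2, 1], 255L)  # the 65535 sample
  expect_equal(vol$intensities[1, 1, 2], 128L)  # the midpoint sample
})

test_that("crop_volume applies the floor rule and validates extents", {
  # 7 x 6 x 1 mm volume at dx=dy=10 um, dz=2 um
  vol <- oct_volume(array(0L, c(500, 600, 700)), vx())
  cropped <- crop_volume(vol, c(1, 1, 0.45))
  expect_identical(dim(cropped$intensities),
                   as.integer(c(floor(450 / 2), floor(1000 / 10),
                                floor(1000 / 10))))
  expect_identical(cropped$voxel, vol$voxel)
  # full-extent crop is the identity
  full <- crop_volume(vol, c(7, 6, 1))
  expect_identical(full$intensities, vol$intensities)
  # oversized request names the axis
  expect_error(crop_volume(vol, c(8, 1, 0.1)), "x-axis")
})

test_that("two successive crops commute with one combined crop", {
  withr::local_seed(11)
  arr <- array(sample(0:255, 40 * 50 * 60, TRUE), c(40, 50, 60))
  vol <- oct_volume(arr, vx())
  a <- crop_volume(crop_volume(vol, c(0.5, 0.4, 0.06)), c(0.3, 0.2, 0.04))
  b <- crop_volume(vol, c(0.3, 0.2, 0.04))
  expect_identical(a$intensities, b$intensities)
  # with an offset origin
  a2 <- crop_volume(crop_volume(vol, c(0.5, 0.4, 0.06), origin = c(5, 4, 3)),
                    c(0.3, 0.2, 0.04), origin = c(2, 1, 1))
  b2 <- crop_volume(vol, c(0.3, 0.2, 0.04), origin = c(7, 5, 4))
  expect_identical(a2$intensities, b2$intensities)
})

test_that("disagreeing TIFF resolution tags trigger a warning, not an override", {
  page <- matrix(0, 8, 8)
  # 5000 px/cm -> 2 um/px; config says dx = 10 um: >1% off, warn
  attr(page, "x.resolution") <- 5000
  attr(page, "resolution.unit") <- "cm"
  expect_warning(
    octbiofilm:::check_resolution_tags(page, vx(dx = 10), "p.tif"),
    "using config")
  # within 1%: silent
  attr(page, "x.resolution") <- 10000 / 10.05
  expect_silent(octbiofilm:::check_resolution_tags(page, vx(dx = 10), "p.tif"))
  # no tags: silent
  expect_silent(octbiofilm:::check_resolution_tags(matrix(0, 2, 2),
                                                   vx(dx = 10), "p.tif"))
})

test_that("target images round-trip through PNG with derived pixel sizes", {
  withr::local_seed(12)
  path <- withr::local_tempfile(fileext = ".png")
  px <- array(sample(0:255, 30 * 40 * 3, TRUE), c(30, 40, 3))
  img <- target_image(px, 6700 / 40, 5000 / 30)
  write_target_image(img, path)
  back <- load_target_image(path, fov_mm = c(6.7, 5.0))
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$px_size_x, 6700 / 40)
  expect_equal(back$px_size_y, 5000 / 30)
})

test_that("voxel JSON sidecars are read into a voxel spec", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"dx": 8, "dy": 8, "dz_air": 2.793, "refractive_index": 1.33}',
             path)
  v <- read_voxel_json(path)
  expect_equal(v$dx, 8)
  expect_equal(dz_eff(v), 2.1, tolerance = 1e-3)
  writeLines('{"dx": 8, "dy": 8}', path)
  expect_error(read_voxel_json(path), "dz_air")
})
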