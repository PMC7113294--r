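test_that("local thickness is the binary column sum scaled by dz", {
  expect_equal(local_thickness(rep(255, 10), 2.1), 21.0)
  expect_equal(local_thickness(rep(0, 10), 2.1), 0)
  # voids do not add thickness under the sum rule
  expect_equal(local_thickness(c(255, 0, 255), 1), 2.0)
  expect_error(local_thickness(c(255, 3), 1), "binary")
  expect_error(local_thickness(rep(255, 3), 0), "dz")
})

test_that("mean thickness averages all columns, empty ones included", {
  # uniform slab: k * dz exactly
  vol <- slab_volume(nz = 12, k = 5, voxel = vx(dz_air = 2.1))
  expect_equal(mean_biofilm_thickness(vol), 5 * 2.1)
  # half slab of 10, half empty at dz = 1
  arr <- array(0L, c(12, 4, 8))
  arr[1:10, , 1:4] <- 255L
  expect_equal(mean_biofilm_thickness(arr, dz = 1), 5.0)
  expect_error(mean_biofilm_thickness(array(integer(0), c(0, 2, 2)), dz = 1))
})

test_that("mean thickness equals the global-sum voxel-counting oracle", {
  withr::local_seed(31)
  for (i in 1:10) {
    bin <- random_binary_volume(10, 7, 9, p = runif(1, 0, 0.8))
    dz <- runif(1, 0.5, 5)
    expect_equal(mean_biofilm_thickness(bin, dz = dz),
                 oracle_mean_thickness(bin, dz))
  }
})

test_that("interface thickness mode counts voids as thickness", {
  arr <- array(0L, c(6, 2, 2))
  arr[c(1, 4), 1, 1] <- 255L   # top at z = 4, two biomass voxels
  expect_equal(mean_biofilm_thickness(arr, dz = 2, mode = "sum"), 2 * 2 / 4)
  expect_equal(mean_biofilm_thickness(arr, dz = 2, mode = "interface"), 4 * 2 / 4)
})

test_that("substratum coverage counts pixels >= 1", {
  expect_equal(substratum_coverage(matrix(0L, 10, 10)), 0)
  expect_equal(substratum_coverage(matrix(255L, 10, 10)), 100)
  half <- matrix(0L, 10, 10); half[, 1:5] <- 1L
  expect_equal(substratum_coverage(half), 50)
  expect_error(substratum_coverage(matrix(integer(0), 0, 0)))
})

test_that("intrinsic porosity is the void share of the biofilm envelope", {
  expect_equal(intrinsic_porosity(three_class_label(slab_volume(k = 4)$intensities)), 0)
  # equal void and biomass counts -> 50%
  arr <- array(0L, c(5, 2, 2))
  arr[c(1, 3), , ] <- 255L          # roof at 3, void at 2: 8 bio, 4 void
  arr[1, , 1] <- 255L
  lab <- three_class_label(arr)
  n_v <- sum(lab$values == 50L); n_b <- sum(lab$values == 150L)
  expect_equal(intrinsic_porosity(lab), 100 * n_v / (n_v + n_b))
  # background-only slices above change nothing
  tall <- array(0L, c(9, 2, 2)); tall[1:5, , ] <- arr
  expect_equal(intrinsic_porosity(three_class_label(tall)),
               intrinsic_porosity(lab))
  # empty volume: undefined
  expect_true(is.na(intrinsic_porosity(three_class_label(array(0L, c(3, 3, 3))))))
})

test_that("global porosity is the non-biomass share below the interface", {
  expect_equal(global_porosity(three_class_label(slab_volume(k = 4)$intensities)), 0)
  # column of height 10 with one internal void voxel -> 10%
  arr <- array(0L, c(12, 3, 3))
  arr[1:10, , ] <- 255L
  arr[5, , ] <- 0L
  expect_equal(global_porosity(three_class_label(arr)), 10)
  expect_true(is.na(global_porosity(three_class_label(array(0L, c(3, 3, 3))))))
})

test_that("porosities match the brute-force counting oracles", {
  withr::local_seed(32)
  for (i in 1:10) {
    bin <- random_binary_volume(9, 6, 8, p = runif(1, 0.05, 0.7))
    lab <- three_class_label(bin)
    expect_equal(intrinsic_porosity(lab), oracle_phi_intrinsic(bin))
    expect_equal(global_porosity(lab), oracle_phi_global(bin))
  }
})

test_that("height maps report the topmost-interface height per column", {
  vol <- slab_volume(nz = 10, k = 6, voxel = vx(dz_air = 2))
  hm <- height_map(vol)
  expect_true(all(hm$heights == 6 * 2))
  # single voxel at z = 10, dz = 2 -> 20 um in that column, 0 elsewhere
  arr <- array(0L, c(10, 4, 4)); arr[10, 2, 3] <- 255L
  hm2 <- height_map(arr, dz = 2)
  expect_equal(hm2$heights[2, 3], 20)
  expect_equal(sum(hm2$heights), 20)
  # bound: never above the channel height
  withr::local_seed(33)
  bin <- random_binary_volume(8, 5, 5, 0.5)
  expect_true(max(height_map(bin, dz = 2.1)$heights) <= 8 * 2.1)
})

test_that("mean thickness is bounded by mean interface height, equal when void-free", {
  vol <- slab_volume(k = 5, voxel = vx(dz_air = 2))
  expect_equal(mean_biofilm_thickness(vol),
               mean(height_map(vol)$heights))
  withr::local_seed(34)
  for (i in 1:8) {
    bin <- random_binary_volume(10, 6, 6, p = runif(1, 0.1, 0.7))
    expect_lte(mean_biofilm_thickness(bin, dz = 2),
               mean(height_map(bin, dz = 2)$heights) + 1e-12)
  }
})

test_that("textural entropy reproduces hand-built co-occurrence tables", {
  expect_equal(textural_entropy(matrix(200L, 16, 16)), 0)
  # width-1 vertical stripes, 5 columns: transitions a->b and b->a each 0.5
  s <- matrix(rep(c(10L, 200L), length.out = 5 * 4), 4, 5, byrow = TRUE)
  expect_equal(textural_entropy(s, c(0, 1)), log(2))
  expect_error(textural_entropy(matrix(1L, 2, 2), c(0, 5)), "offset")
  expect_error(textural_entropy(matrix(1L, 2, 2), c(0, 0)), "nonzero")
})

test_that("textural entropy equals the naive pixel-pair loop oracle", {
  withr::local_seed(35)
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    img <- random_image(10, 12, levels = 0:7 * 30)
    expect_equal(textural_entropy(img, off), oracle_te(img, off),
                 info = paste(off, collapse = ","))
  }
})

test_that("textural entropy is invariant under intensity bijections and transposition", {
  withr::local_seed(36)
  img <- random_image(12, 12, levels = c(3L, 60L, 120L, 250L))
  te <- textural_entropy(img, c(0, 1))
  # relabel by a random permutation of the gray levels
  perm <- sample(0:255)
  relab <- matrix(perm[img + 1L], nrow(img))
  expect_equal(textural_entropy(relab, c(0, 1)), te)
  # reversed offset equals the transposed co-occurrence: same entropy
  expect_equal(textural_entropy(img, c(0, -1)), te)
  # axis swap maps offset (0,1) to (1,0)
  expect_equal(textural_entropy(t(img), c(1, 0)), te)
})

test_that("structural parameters are invariant under swapping the lateral axes", {
  withr::local_seed(37)
  bin <- random_binary_volume(8, 6, 9, p = 0.4)
  swapped <- aperm(bin, c(1, 3, 2))
  expect_equal(mean_biofilm_thickness(bin, dz = 2),
               mean_biofilm_thickness(swapped, dz = 2))
  expect_equal(substratum_coverage(max_intensity_projection(bin)),
               substratum_coverage(max_intensity_projection(swapped)))
  expect_equal(intrinsic_porosity(three_class_label(bin)),
               intrinsic_porosity(three_class_label(swapped)))
  expect_equal(global_porosity(three_class_label(bin)),
               global_porosity(three_class_label(swapped)))
})

test_that("coverage and thickness are monotone under adding biomass", {
  withr::local_seed(38)
  bin <- random_binary_volume(8, 6, 6, p = 0.2)
  more <- bin
  zeros <- which(more == 0L)
  more[sample(zeros, length(zeros) %/% 4)] <- 255L
  expect_gte(substratum_coverage(max_intensity_projection(more)),
             substratum_coverage(max_intensity_projection(bin)))
  expect_gte(mean_biofilm_thickness(more, dz = 2),
             mean_biofilm_thickness(bin, dz = 2))
})

test_that("structure_report composes the pipeline on known volumes", {
  # solid slab: SC 100, porosities 0, TE 0, thickness = slab height
  vol <- slab_volume(nz = 10, ny = 12, nx = 12, k = 6, voxel = vx(dz_air = 2))
  rep <- structure_report(vol)
  expect_equal(rep$sc_percent, 100)
  expect_equal(rep$mean_thickness_um, 12)
  expect_equal(rep$phi_intrinsic_percent, 0)
  expect_equal(rep$phi_global_percent, 0)
  expect_equal(rep$textural_entropy, 0)
  expect_equal(rep$n_columns, 144)
  # empty channel: zero coverage, zero thickness, porosities undefined
  empty <- oct_volume(array(0L, c(10, 12, 12)), vx())
  rep0 <- structure_report(empty)
  expect_equal(rep0$sc_percent, 0)
  expect_equal(rep0$mean_thickness_um, 0)
  expect_true(is.na(rep0$phi_intrinsic_percent))
  expect_true(is.na(rep0$phi_global_percent))
  expect_equal(rep0$textural_entropy, 0)
  # settings are recorded for reproducibility
  expect_equal(attr(rep, "params")$filter_radius, 2L)
  expect_s3_class(attr(rep, "height_map"), "height_map")
})
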