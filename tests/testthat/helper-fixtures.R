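# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures on disk.

# voxel spec with unit-friendly numbers for hand computation
vx <- function(dx = 10, dy = 10, dz_air = 2, n = 1) {
  voxel_spec(dx, dy, dz_air, refractive_index = n)
}

# solid slab volume: biomass 255 for z in 1..k, zeros above
slab_volume <- function(nz = 10, ny = 8, nx = 8, k = 4, voxel = vx()) {
  arr <- array(0L, c(nz, ny, nx))
  if (k > 0) arr[seq_len(k), , ] <- 255L
  oct_volume(arr, voxel)
}

# random binary (0/255) volume with given foreground probability
random_binary_volume <- function(nz, ny, nx, p = 0.3) {
  array(ifelse(runif(nz * ny * nx) < p, 255L, 0L), c(nz, ny, nx))
}

# random 8-bit image
random_image <- function(h, w, levels = 0:255) {
  matrix(sample(levels, h * w, replace = TRUE), h, w)
}

# --- independent brute-force oracles (naive loops, no package code) -----

# disc mean filter by direct enumeration with edge replication
oracle_disc_mean <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      if (dy * dy + dx * dx > r * r) next
      y <- min(max(i + dy, 1), H)
      x <- min(max(j + dx, 1), W)
      vals <- c(vals, img[y, x])
    }
    out[i, j] <- floor(mean(vals) + 0.5)
  }
  storage.mode(out) <- "integer"
  out
}

# structural parameters by direct voxel counting on a binary volume
oracle_mean_thickness <- function(bin, dz) {
  d <- dim(bin)
  total <- 0
  for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    total <- total + sum(bin[, y, x]) / 255
  total * dz / (d[2] * d[3])
}

oracle_sc <- function(mip) {
  n <- 0
  for (i in seq_len(nrow(mip))) for (j in seq_len(ncol(mip)))
    if (mip[i, j] >= 1) n <- n + 1
  100 * n / length(mip)
}

# column-rule three-class counts: biofilm / void voxel totals
oracle_label_counts <- function(bin) {
  d <- dim(bin)
  n_bio <- 0; n_void <- 0
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    col <- bin[, y, x]
    top <- if (any(col == 255)) max(which(col == 255)) else 0
    n_bio <- n_bio + sum(col == 255)
    if (top > 1) n_void <- n_void + sum(col[seq_len(top - 1)] == 0)
  }
  c(biofilm = n_bio, void = n_void)
}

oracle_phi_intrinsic <- function(bin) {
  n <- oracle_label_counts(bin)
  if (sum(n) == 0) return(NA_real_)
  100 * n[["void"]] / sum(n)
}

oracle_phi_global <- function(bin) {
  d <- dim(bin)
  below <- 0; n_bio <- 0
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    col <- bin[, y, x]
    top <- if (any(col == 255)) max(which(col == 255)) else 0
    below <- below + top
    n_bio <- n_bio + sum(col == 255)
  }
  if (below == 0) return(NA_real_)
  100 * (below - n_bio) / below
}

# co-occurrence textural entropy by a naive double loop over pixel pairs
oracle_te <- function(img, offset = c(0, 1)) {
  H <- nrow(img); W <- ncol(img)
  counts <- new.env()
  n <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    i2 <- i + offset[1]; j2 <- j + offset[2]
    if (i2 < 1 || i2 > H || j2 < 1 || j2 > W) next
    key <- paste(img[i, j], img[i2, j2])
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    n <- n + 1
  }
  p <- unlist(as.list(counts)) / n
  -sum(p * log(p))
}
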