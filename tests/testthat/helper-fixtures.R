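# Shared in-code fixtures: all test inputs are generated here, none stored.

# Filled-ellipse intensity image (background 0, foreground `value`).
ellipse_image <- function(ny, nx, pixel_size, center, a, b, angle = 0, value = 1) {
  m <- matrix(0, ny, nx)
  pcx <- (seq_len(nx) - 0.5) * pixel_size
  pcy <- (seq_len(ny) - 0.5) * pixel_size
  X <- matrix(pcx, ny, nx, byrow = TRUE) - center[1]
  Y <- matrix(pcy, ny, nx, byrow = FALSE) - center[2]
  u <- X * cos(angle) + Y * sin(angle)
  v <- -X * sin(angle) + Y * cos(angle)
  m[(u / a)^2 + (v / b)^2 <= 1] <- value
  m
}

# Disk image helper (circle special case).
disk_image <- function(ny, nx, pixel_size, center, r, value = 1) {
  ellipse_image(ny, nx, pixel_size, center, r, r, 0, value)
}

# Brute-force Otsu oracle: exhaustive scan of candidate thresholds for the
# maximum between-class variance (independent of the EBImage path).
otsu_bruteforce <- function(v) {
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]
  best <- -Inf; best_t <- cand[1]
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; best_t <- t }
  }
  best_t
}

# Tiny deterministic multi-channel stack for I/O tests.
toy_stack <- function(ny = 16, nx = 12, nz = 5, n_ch = 2, seed = 123,
                      integer_data = TRUE) {
  set.seed(seed)
  chans <- lapply(seq_len(n_ch), function(i) {
    v <- if (integer_data) rpois(ny * nx * nz, 40) else runif(ny * nx * nz, 0, 7)
    array(v, c(ny, nx, nz))
  })
  names(chans) <- paste0("marker", seq_len(n_ch))
  calibrated_stack(chans, pixel_size_xy = 0.08, z_step = 0.4)
}

scene_defaults_small <- function() {
  cfg <- contact_config()
  cfg$puncta_count_mean <- 14
  cfg$puncta_count_sd <- 2
  cfg
}
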