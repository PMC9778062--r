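# Shared fixtures, built in code. Expensive objects are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

flat_image <- function(value = c(120, 130, 140), n = 60) {
  px <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) px[, , ch] <- value[ch]
  well_image(px)
}

# Noise-free rendering: the disk color is exact inside the disk.
noisefree_render <- function() {
  render_params(lighting_gain_sd = 0, pixel_noise_sd = 0,
                conc_jitter_sd = 0, vignette_strength = 0)
}

# A clean disk image with known geometry for detection oracles.
disk_fixture <- function(color = c(180, 70, 130), seed = 11,
                         rp = noisefree_render()) {
  render_well_image(color, rp, seed = seed)
}

# Small end-to-end calibration shared across tests: 12 levels x 8 images.
small_calibration <- function() {
  memo("small_cal", {
    cfg <- pipeline_config(master_seed = 401,
                           generator = list(n_per_group = 8))
    calibrate_assay(cfg)
  })
}

# The full default calibration run (12 levels x 100 images, default seeds).
# Expensive (~1.5 min); memoized and shared by the acceptance criteria.
default_calibration <- function() {
  memo("default_cal", calibrate_assay(pipeline_config()))
}

# Naive two-pass oracle for the color moments, kept deliberately different
# from the package implementation (explicit loops over pixels).
naive_moments <- function(px) {
  out <- numeric(9)
  for (ch in 1:3) {
    v <- c()
    for (y in seq_len(dim(px)[1]))
      for (x in seq_len(dim(px)[2]))
        v <- c(v, px[y, x, ch])
    m1 <- sum(v) / length(v)
    s2 <- 0; s3 <- 0
    for (p in v) {
      s2 <- s2 + (p - m1)^2
      s3 <- s3 + (p - m1)^3
    }
    m2 <- sqrt(s2 / length(v))
    c3 <- s3 / length(v)
    out[(ch - 1) * 3 + 1:3] <- c(m1, m2, sign(c3) * abs(c3)^(1 / 3))
  }
  out
}

# Brute-force circle Hough accumulator: votes for every (cy, cx, r) triple.
brute_hough_votes <- function(edge, rmin, rmax) {
  H <- nrow(edge); W <- ncol(edge)
  ep <- which(edge, arr.ind = TRUE)
  arr <- array(0L, c(H, W, rmax - rmin + 1))
  for (cy in 0:(H - 1)) {
    for (cx in 0:(W - 1)) {
      d <- round(sqrt((ep[, 1] - 1 - cy)^2 + (ep[, 2] - 1 - cx)^2))
      for (r in rmin:rmax)
        arr[cy + 1, cx + 1, r - rmin + 1] <- sum(d == r)
    }
  }
  arr
}
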