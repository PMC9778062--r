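test_that("median filter removes impulses and preserves flats", {
  flat <- flat_image(c(50, 100, 150), n = 10)
  expect_equal(median_filter(flat, 3)$pixels, flat$pixels)

  # 3x3 patch with a hot center: median of nine values is 0
  px <- array(0, dim = c(3, 3, 3))
  px[2, 2, ] <- 255
  out <- median_filter(well_image(px), 3)
  expect_equal(out$pixels[2, 2, ], c(0, 0, 0))

  # isolated hot pixel in a flat field disappears entirely
  px <- array(80, dim = c(9, 9, 3))
  px[5, 5, 1] <- 255
  out <- median_filter(well_image(px), 3)
  expect_true(all(out$pixels == 80))

  expect_error(median_filter(flat, 4), "odd")
  expect_error(median_filter(flat, 11), "exceeds")
})

test_that("gaussian filter is a normalized truncated kernel with reflect padding", {
  flat <- flat_image(c(33, 66, 99), n = 12)
  out <- gaussian_filter(flat, 1.5)
  expect_equal(out$pixels, flat$pixels, tolerance = 1e-12)

  # unit impulse reproduces the kernel: direct convolution oracle
  sigma <- 1.0
  rad <- ceiling(3 * sigma)
  w <- exp(-0.5 * ((-rad:rad) / sigma)^2); w <- w / sum(w)
  kern2d <- outer(w, w)
  n <- 15
  px <- array(0, dim = c(n, n, 3))
  px[8, 8, ] <- 1
  out <- gaussian_filter(well_image(px), sigma)
  got <- out$pixels[(8 - rad):(8 + rad), (8 - rad):(8 + rad), 2]
  expect_equal(got, kern2d, tolerance = 1e-12)
  expect_equal(max(out$pixels[, , 1]), max(kern2d))
  expect_equal(which.max(out$pixels[, , 1]), (8 - 1) * n + 8)

  # smoothing never increases per-channel variance
  set.seed(8)
  px <- array(runif(20 * 20 * 3, 0, 255), dim = c(20, 20, 3))
  sm <- gaussian_filter(well_image(px), 2)
  for (ch in 1:3) expect_lte(var(as.vector(sm$pixels[, , ch])),
                             var(as.vector(px[, , ch])))

  expect_error(gaussian_filter(flat, 0), "positive")
})

test_that("hough detection recovers a noise-free disk to within a pixel", {
  img <- disk_fixture(seed = 21)
  det <- hough_detect_circle(img)
  expect_s3_class(det, "circle_detection")
  expect_lt(abs(det$cx - attr(img, "center")["x"]), 1 + 1e-9)
  expect_lt(abs(det$cy - attr(img, "center")["y"]), 1 + 1e-9)
  expect_lt(abs(det$r - attr(img, "radius")), 1 + 1e-9)
})

test_that("hough detection fails cleanly on blank images", {
  expect_error(hough_detect_circle(flat_image(c(128, 128, 128))),
               "segmentation failure")
})

test_that("hough detection tolerates default rendering noise", {
  rp <- render_params()
  img <- render_well_image(c(150, 70, 140), rp, seed = 77)
  det <- hough_detect_circle(img)
  expect_lt(abs(det$r - attr(img, "radius")), 2 + 1e-9)
})

test_that("accumulator equals exhaustive search on small fixtures", {
  rp <- render_params(image_size = 50, well_radius_mean = 14,
                      well_radius_jitter = 2, center_jitter = 3,
                      lighting_gain_sd = 0, pixel_noise_sd = 2,
                      conc_jitter_sd = 0, vignette_strength = 0)
  img <- render_well_image(c(150, 70, 140), rp, seed = 3)
  gray <- aptacolor:::cpp_median_filter(aptacolor:::rgb_to_gray(img$pixels), 5L)
  mag <- aptacolor:::cpp_sobel_magnitude(gray)
  edge <- mag > max(aptacolor:::otsu_threshold(mag), 1e-6)
  votes <- aptacolor:::cpp_hough_votes(edge, 10L, 18L)
  brute <- brute_hough_votes(edge, 10L, 18L)
  expect_equal(as.integer(votes), as.integer(brute))
  # and the argmax is the detected circle
  det <- hough_detect_circle(img, preprocess_config(hough_radius_min = 10,
                                                    hough_radius_max = 18))
  expect_equal(det$score, max(brute))
})

test_that("geometric recovery holds over 50 seeded default-noise fixtures", {
  errs <- t(vapply(1:50, function(s) {
    img <- render_well_image(c(160, 75, 135), render_params(), seed = 9000 + s)
    det <- hough_detect_circle(img)
    c(center = sqrt((det$cx - attr(img, "center")["x"])^2 +
                    (det$cy - attr(img, "center")["y"])^2),
      radius = abs(det$r - attr(img, "radius")))
  }, c(center = 0, radius = 0)))
  expect_lte(median(errs[, "center"]), 1)
  expect_lte(median(errs[, "radius"]), 2)
})

test_that("cropping extracts the inscribed square", {
  img <- disk_fixture(color = c(150, 70, 140), seed = 13)
  det <- hough_detect_circle(img)
  crop <- crop_to_square(img, det, 50)
  expect_equal(dim(crop$pixels), c(50, 50, 3))
  # inscribed square contains only disk pixels
  expect_equal(as.vector(apply(crop$pixels, 3, range)),
               c(150, 150, 70, 70, 140, 140))

  # identity resampling: size equal to a grid-aligned inscribed side
  px <- array(0, dim = c(40, 40, 3))
  for (ch in 1:3) px[, , ch] <- matrix(seq_len(1600) %% 200, 40, 40) + ch
  src <- well_image(px)
  det0 <- structure(list(cx = 20, cy = 20, r = 10 * sqrt(2), score = 1),
                    class = "circle_detection")
  out <- crop_to_square(src, det0, 20)  # side = 20, aligned at (10, 10)
  expect_equal(out$pixels, px[11:30, 11:30, ], tolerance = 1e-12)

  big <- structure(list(cx = 5, cy = 5, r = 30, score = 1),
                   class = "circle_detection")
  expect_error(crop_to_square(src, big, 20), "bounds")
})

test_that("full preprocessing emits a deterministic 50x50 crop of the disk color", {
  img <- disk_fixture(color = c(150, 70, 140), seed = 29)
  out1 <- preprocess_well(img)
  out2 <- preprocess_well(img)
  expect_identical(out1$pixels, out2$pixels)
  expect_equal(dim(out1$pixels), c(50, 50, 3))
  expect_s3_class(attr(out1, "detection"), "circle_detection")
  expect_equal(unname(apply(out1$pixels, 3, mean)), c(150, 70, 140),
               tolerance = 0.02)
})
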