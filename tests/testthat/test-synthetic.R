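test_that("aggregation fraction follows the Hill dose-response", {
  p <- dose_response_params(ec50 = 0.7, hill_n = 1)
  expect_equal(aggregation_fraction(0, p), 0)
  expect_equal(aggregation_fraction(0.7, p), 0.5)
  expect_equal(aggregation_fraction(3.9, p), 3.9 / 4.6, tolerance = 1e-12)
  # midpoint holds for any parameters
  p2 <- dose_response_params(ec50 = 1.3, hill_n = 2.7)
  expect_equal(aggregation_fraction(1.3, p2), 0.5)
  # strictly increasing and bounded in [0, 1)
  cs <- seq(0, 50, by = 0.25)
  f <- aggregation_fraction(cs, p2)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
  expect_error(aggregation_fraction(-0.1, p), "non-negative")
})

test_that("solution color interpolates the endpoint colors", {
  cm <- color_model(dispersed_rgb = c(200, 60, 120),
                    aggregated_rgb = c(100, 80, 160))
  expect_equal(solution_color(0, cm), c(200, 60, 120))
  expect_equal(solution_color(1, cm), c(100, 80, 160))
  expect_equal(solution_color(0.5, cm), c(150, 70, 140))
  # each channel affine in f
  f <- c(0.2, 0.4, 0.8)
  cols <- t(vapply(f, solution_color, numeric(3), cm = cm))
  expect_equal(cols[, 1], 200 - 100 * f)
  expect_error(solution_color(1.2, cm), "\\[0, 1\\]")
  expect_error(color_model(c(10, 10, 10), c(10, 10, 10)), "differ")
})

test_that("spectral ratio maps the aggregation fraction affinely", {
  p <- dose_response_params(ratio_min = 0.2, ratio_max = 1.0)
  expect_equal(spectral_ratio(0, p), 0.2)
  expect_equal(spectral_ratio(1, p), 1.0)
  expect_equal(spectral_ratio(0.25, p), 0.4)
  expect_error(spectral_ratio(-0.01, p), "\\[0, 1\\]")
})

test_that("rendering is seeded-deterministic and exact in the noise-free limit", {
  rp <- render_params()
  a <- render_well_image(c(150, 70, 140), rp, seed = 42)
  b <- render_well_image(c(150, 70, 140), rp, seed = 42)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(
    a$pixels, render_well_image(c(150, 70, 140), rp, seed = 43)$pixels))

  img <- disk_fixture(color = c(150, 70, 140), seed = 5)
  ctr <- attr(img, "center"); r <- attr(img, "radius")
  n <- nrow(img$pixels)
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  inside <- (xs - ctr["x"])^2 + (ys - ctr["y"])^2 <= r^2
  for (ch in 1:3) {
    plane <- img$pixels[, , ch]
    expect_true(all(plane[inside] == c(150, 70, 140)[ch]))
  }
})

test_that("mean disk color under default noise stays near the requested color", {
  rp <- render_params(conc_jitter_sd = 0)  # optical noise only
  img <- render_well_image(c(150, 70, 140), rp, seed = 12)
  ctr <- attr(img, "center"); r <- attr(img, "radius")
  n <- nrow(img$pixels)
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), times = n), n, n)
  inside <- (xs - ctr["x"])^2 + (ys - ctr["y"])^2 <= (r - 2)^2
  expect_gt(sum(inside), 500)
  for (ch in 1:3) {
    expect_lt(abs(mean(img$pixels[, , ch][inside]) - c(150, 70, 140)[ch]), 3)
  }
})

test_that("render rejects wells that can leave the frame", {
  expect_error(render_params(image_size = 60, well_radius_mean = 25,
                             well_radius_jitter = 5, center_jitter = 5),
               "exceed the frame")
})

test_that("generate_dataset respects the design and is reproducible", {
  ds <- generate_dataset(c(0, 0.5, 3.9), n_per_group = 4, master_seed = 9)
  expect_length(ds$images, 12)
  expect_equal(ds$manifest$concentration_uM,
               rep(c(0, 0.5, 3.9), each = 4))
  # label conservation
  expect_equal(vapply(ds$images, function(im) im$true_conc, numeric(1)),
               ds$manifest$concentration_uM)
  ds2 <- generate_dataset(c(0, 0.5, 3.9), n_per_group = 4, master_seed = 9)
  expect_identical(lapply(ds$images, `[[`, "pixels"),
                   lapply(ds2$images, `[[`, "pixels"))

  one <- generate_dataset(1.1, n_per_group = 1, master_seed = 2)
  expect_length(one$images, 1)
  expect_equal(one$images[[1]]$true_conc, 1.1)

  expect_warning(generate_dataset(c(1, 1), n_per_group = 1, master_seed = 1),
                 "duplicate")
  expect_error(generate_dataset(c(1, -1), n_per_group = 1, master_seed = 1),
               "non-negative")
})

test_that("noise-free blue-red contrast is monotone in concentration", {
  # default color model: B increases, R decreases with aggregation
  cm <- color_model()
  rp <- noisefree_render()
  dose <- dose_response_params()
  levels <- default_concentrations()
  bmr <- vapply(seq_along(levels), function(i) {
    col <- solution_color(aggregation_fraction(levels[i], dose), cm)
    img <- render_well_image(col, rp, seed = 100 + i)
    crop <- preprocess_well(img)
    mean(crop$pixels[, , 3]) - mean(crop$pixels[, , 1])
  }, numeric(1))
  expect_true(all(diff(bmr) > 0))
})

test_that("datasets round-trip through PNG files and a manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(c(0, 2.3), n_per_group = 2, master_seed = 31)
  man <- write_dataset(ds, dir)
  expect_setequal(c("filename", "concentration_uM", "group_index",
                    "replicate_index", "seed"), names(man))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "\\.png$"), 4)
  back <- read_well_png(file.path(dir, man$filename[1]))
  expect_equal(back$pixels, ds$images[[1]]$pixels)
})
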