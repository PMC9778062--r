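#' Dose-response parameters for the synthetic generator
#'
#' The generator links amoxicillin concentration to AuNP aggregation with a
#' Hill curve: `f(c) = c^n / (c^n + ec50^n)`. The aggregation fraction `f`
#' drives both the rendered solution color and the surrogate A620/A520
#' absorbance ratio. All numeric defaults are generator choices, calibrated
#' once so that the full synthetic pipeline matches the fit quality reported
#' for real scanner images; they are not measured physical constants.
#'
#' @param ec50 concentration (uM) at which half the particles are aggregated.
#' @param hill_n Hill cooperativity exponent (> 0).
#' @param ratio_min,ratio_max endpoints of the surrogate A620/A520 absorbance
#'   ratio for fully dispersed (`f = 0`) and fully aggregated (`f = 1`)
#'   particles; `ratio_min < ratio_max`.
#' @return A list of class `dose_response_params`.
#' @export
#' @examples
#' p <- dose_response_params()
#' aggregation_fraction(c(0, 0.7, 3.9), p)
dose_response_params <- function(ec50 = 0.7, hill_n = 1.2,
                                 ratio_min = 0.2, ratio_max = 1.1) {
  stopifnot(ec50 > 0, hill_n > 0, ratio_min < ratio_max)
  structure(list(ec50 = ec50, hill_n = hill_n,
                 ratio_min = ratio_min, ratio_max = ratio_max),
            class = "dose_response_params")
}

#' Endpoint colors of the colorimetric reaction
#'
#' Dispersed AuNPs appear purple-red; salt-aggregated particles appear
#' blue-purple. The rendered solution color is a channel-wise linear
#' interpolation between these two endpoints, weighted by the aggregation
#' fraction.
#'
#' @param dispersed_rgb,aggregated_rgb RGB triples in `[0, 255]` for the
#'   fully dispersed and fully aggregated solution.
#' @return A list of class `color_model`.
#' @export
color_model <- function(dispersed_rgb = c(200, 60, 120),
                        aggregated_rgb = c(100, 80, 160)) {
  stopifnot(length(dispersed_rgb) == 3L, length(aggregated_rgb) == 3L,
            all(dispersed_rgb >= 0 & dispersed_rgb <= 255),
            all(aggregated_rgb >= 0 & aggregated_rgb <= 255))
  if (all(dispersed_rgb == aggregated_rgb))
    stop("endpoint colors must differ in at least one channel")
  structure(list(dispersed_rgb = as.numeric(dispersed_rgb),
                 aggregated_rgb = as.numeric(aggregated_rgb)),
            class = "color_model")
}

#' Rendering parameters for synthetic well images
#'
#' Controls the geometry and nuisance variation of the rendered well: the
#' solution disk is drawn at a jittered center and radius on a flat
#' background, modulated by a radial vignette and a per-image multiplicative
#' lighting gain, then corrupted with per-pixel additive Gaussian noise and
#' clipped to `[0, 255]`. Defaults emulate a small scanner capture; the noise
#' levels are the calibrated values under which the default pipeline attains
#' its reference fit quality.
#'
#' @param image_size image side length in pixels (square frame).
#' @param well_radius_mean,well_radius_jitter disk radius mean and uniform
#'   half-range, pixels.
#' @param center_jitter uniform half-range of the disk center around the frame
#'   center, pixels.
#' @param lighting_gain_sd standard deviation of the per-image multiplicative
#'   lighting gain, drawn independently per color channel
#'   (gain_ch ~ `1 + N(0, sd)`) to emulate illumination color-temperature
#'   drift between captures.
#' @param pixel_noise_sd standard deviation of per-pixel additive Gaussian
#'   noise, intensity units.
#' @param conc_jitter_sd per-image standard deviation (uM) of the effective
#'   dose driving the aggregation reaction, emulating replicate-to-replicate
#'   chemistry variability (pipetting, incubation, salt addition). Unlike the
#'   optical noise terms this error is irreducible by any image analysis, so
#'   it sets the floor of the achievable prediction error.
#' @param background_rgb background color triple in `[0, 255]`.
#' @param vignette_strength radial intensity falloff at the frame corners,
#'   in `[0, 1)`.
#' @return A list of class `render_params`.
#' @export
render_params <- function(image_size = 100,
                          well_radius_mean = 32, well_radius_jitter = 4,
                          center_jitter = 5,
                          lighting_gain_sd = 0.005,
                          pixel_noise_sd = 4,
                          conc_jitter_sd = 0.2,
                          background_rgb = c(235, 235, 235),
                          vignette_strength = 0.08) {
  stopifnot(image_size >= 50, well_radius_mean > 0, well_radius_jitter >= 0,
            center_jitter >= 0, lighting_gain_sd >= 0, pixel_noise_sd >= 0,
            conc_jitter_sd >= 0, length(background_rgb) == 3L,
            vignette_strength >= 0, vignette_strength < 1)
  max_extent <- well_radius_mean + well_radius_jitter + center_jitter
  if (max_extent > image_size / 2 - 1)
    stop("well can exceed the frame after maximal jitter; ",
         "reduce radius/jitter or enlarge image_size")
  structure(list(image_size = as.integer(image_size),
                 well_radius_mean = well_radius_mean,
                 well_radius_jitter = well_radius_jitter,
                 center_jitter = center_jitter,
                 lighting_gain_sd = lighting_gain_sd,
                 pixel_noise_sd = pixel_noise_sd,
                 conc_jitter_sd = conc_jitter_sd,
                 background_rgb = as.numeric(background_rgb),
                 vignette_strength = vignette_strength),
            class = "render_params")
}

#' Aggregation fraction at a given concentration
#'
#' Hill dose-response `f = c^n / (c^n + ec50^n)`: zero at zero dose, strictly
#' increasing, saturating towards 1.
#'
#' @param c concentration(s) in uM, non-negative.
#' @param p a [dose_response_params()].
#' @return Aggregation fraction(s) in `[0, 1)`.
#' @export
aggregation_fraction <- function(c, p = dose_response_params()) {
  if (any(c < 0)) stop("concentration must be non-negative")
  cn <- c^p$hill_n
  cn / (cn + p$ec50^p$hill_n)
}

#' Solution color at a given aggregation fraction
#'
#' Channel-wise affine interpolation between the dispersed and aggregated
#' endpoint colors.
#'
#' @param f aggregation fraction in `[0, 1]`.
#' @param cm a [color_model()].
#' @return RGB triple (numeric length 3).
#' @export
solution_color <- function(f, cm = color_model()) {
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("aggregation fraction must be a single value in [0, 1]")
  (1 - f) * cm$dispersed_rgb + f * cm$aggregated_rgb
}

#' Surrogate A620/A520 absorbance ratio
#'
#' Affine map of the aggregation fraction onto the configured absorbance-ratio
#' endpoints; stands in for the spectral aggregation index of the real assay.
#'
#' @inheritParams solution_color
#' @param p a [dose_response_params()].
#' @return Dimensionless ratio in `[ratio_min, ratio_max]`.
#' @export
spectral_ratio <- function(f, p = dose_response_params()) {
  if (any(is.na(f)) || any(f < 0) || any(f > 1))
    stop("aggregation fraction must lie in [0, 1]")
  p$ratio_min + f * (p$ratio_max - p$ratio_min)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  force(code)
}

#' Render one synthetic well image
#'
#' Draws a disk of the requested solution color at a jittered center and
#' radius on the configured background, applies a radial vignette and a
#' per-image multiplicative lighting gain (independent per channel), adds
#' per-pixel Gaussian noise,
#' clips to `[0, 255]` and rounds to 8-bit intensities. The output is a pure
#' function of `(color, rp, seed)`; the caller's RNG state is left untouched.
#'
#' @param color RGB triple to fill the disk with.
#' @param rp a [render_params()].
#' @param seed integer seed controlling all stochastic elements.
#' @return A [well_image()] with attributes `center` (x, y; 0-based) and
#'   `radius` recording the true rendered geometry.
#' @export
render_well_image <- function(color, rp = render_params(), seed = 1L) {
  stopifnot(length(color) == 3L, all(color >= 0 & color <= 255))
  n <- rp$image_size
  with_preserved_rng({
    set.seed(as.integer(seed))
    cx <- (n - 1) / 2 + runif(1, -rp$center_jitter, rp$center_jitter)
    cy <- (n - 1) / 2 + runif(1, -rp$center_jitter, rp$center_jitter)
    r <- rp$well_radius_mean +
      runif(1, -rp$well_radius_jitter, rp$well_radius_jitter)
    gain <- 1 + rnorm(3, 0, rp$lighting_gain_sd)

    xs <- matrix(rep(0:(n - 1), each = n), n, n)   # column index (x)
    ys <- matrix(rep(0:(n - 1), times = n), n, n)  # row index (y)
    inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2

    d2 <- ((xs - (n - 1) / 2)^2 + (ys - (n - 1) / 2)^2) / (2 * ((n - 1) / 2)^2)
    vig <- 1 - rp$vignette_strength * d2

    px <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) {
      plane <- matrix(rp$background_rgb[ch], n, n)
      plane[inside] <- color[ch]
      plane <- plane * vig * gain[ch]
      if (rp$pixel_noise_sd > 0)
        plane <- plane + rnorm(n * n, 0, rp$pixel_noise_sd)
      px[, , ch] <- plane
    }
    px <- round(pmin(pmax(px, 0), 255))
    out <- well_image(px, seed_tag = as.character(seed))
    attr(out, "center") <- c(x = cx, y = cy)
    attr(out, "radius") <- r
    out
  })
}

#' Default concentration design of the assay
#'
#' The twelve calibration levels spanning the physiological range of
#' amoxicillin in breast milk, 0 to 3.9 uM.
#'
#' @return Numeric vector of 12 concentrations in uM.
#' @export
default_concentrations <- function() {
  c(0, 0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 1.1, 1.5, 2.3, 3.1, 3.9)
}

# Deterministic per-image seed: stable under reordering of generation calls.
image_seed <- function(master_seed, group_index, replicate_index) {
  (as.double(master_seed) + 1000003 * group_index + 10007 * replicate_index) %%
    2147483629
}

# Per-image effective dose: chemistry jitter around the nominal concentration,
# drawn from a seed decoupled from the render seed, truncated at zero.
effective_dose <- function(conc, sd, img_seed) {
  if (sd <= 0) return(conc)
  with_preserved_rng({
    set.seed(as.integer((as.double(img_seed) + 777767777) %% 2147483629))
    max(conc + rnorm(1, 0, sd), 0)
  })
}

#' Generate a synthetic calibration dataset
#'
#' Renders `n_per_group` well images at every concentration level. Each image
#' gets its own seed derived deterministically from `master_seed` and its
#' (group, replicate) position, so regeneration with the same master seed is
#' bit-identical and independent of generation order.
#'
#' @param concentrations concentration design in uM (non-negative).
#' @param n_per_group images per concentration level.
#' @param dose a [dose_response_params()].
#' @param colors a [color_model()].
#' @param render a [render_params()].
#' @param master_seed integer master seed.
#' @return A list of class `synthetic_dataset` with elements `images` (list of
#'   [well_image()]), `concentrations`, `n_per_group`, `master_seed`, and
#'   `manifest` (data frame with group/replicate/seed bookkeeping).
#' @export
#' @examples
#' ds <- generate_dataset(c(0, 3.9), n_per_group = 2, master_seed = 7)
#' length(ds$images)
generate_dataset <- function(concentrations = default_concentrations(),
                             n_per_group = 100,
                             dose = dose_response_params(),
                             colors = color_model(),
                             render = render_params(),
                             master_seed = 1L) {
  if (length(concentrations) == 0L) stop("concentration design is empty")
  if (any(concentrations < 0)) stop("concentration levels must be non-negative")
  if (anyDuplicated(concentrations))
    warning("duplicate concentration levels in the design")
  stopifnot(n_per_group >= 1)

  manifest <- expand.grid(replicate_index = seq_len(n_per_group),
                          group_index = seq_along(concentrations))
  manifest <- manifest[, c("group_index", "replicate_index")]
  manifest$concentration_uM <- concentrations[manifest$group_index]
  manifest$seed <- image_seed(master_seed, manifest$group_index,
                              manifest$replicate_index)

  images <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    c_eff <- effective_dose(manifest$concentration_uM[i],
                            render$conc_jitter_sd, manifest$seed[i])
    col <- solution_color(aggregation_fraction(c_eff, dose), colors)
    img <- render_well_image(col, render, manifest$seed[i])
    img$true_conc <- manifest$concentration_uM[i]
    images[[i]] <- img
  }
  structure(list(images = images,
                 concentrations = concentrations,
                 n_per_group = as.integer(n_per_group),
                 master_seed = master_seed,
                 manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d images, %d levels x %d per group, master seed %s>\n",
              length(x$images), length(x$concentrations), x$n_per_group,
              format(x$master_seed)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one 8-bit RGB PNG per image plus a `manifest.csv` with columns
#' `filename`, `concentration_uM`, `group_index`, `replicate_index`, `seed`.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- ds$manifest
  manifest$filename <- sprintf("well_g%02d_r%03d.png",
                               manifest$group_index, manifest$replicate_index)
  for (i in seq_len(nrow(manifest)))
    write_well_png(ds$images[[i]], file.path(dir, manifest$filename[i]))
  manifest <- manifest[, c("filename", "concentration_uM", "group_index",
                           "replicate_index", "seed")]
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
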