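#' Pipeline configuration
#'
#' A single nested configuration covering every stage of the assay pipeline:
#' the synthetic generator (concentration design, dose-response, endpoint
#' colors, rendering), preprocessing, the network, and the train/test split.
#' All defaults are overridable; the object round-trips losslessly through its
#' YAML file representation.
#'
#' @param master_seed integer master seed; all stage seeds (per-image render
#'   seeds, the split seed, the weight-initialization seed) derive from it
#'   deterministically.
#' @param generator,preprocess,network,split named lists of overrides for the
#'   corresponding stage defaults (see [dose_response_params()],
#'   [color_model()], [render_params()], [preprocess_config()], [bpann()],
#'   [split_spec()]).
#' @return A nested list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(master_seed = 7,
#'                        generator = list(n_per_group = 5))
#' cfg$generator$n_per_group
pipeline_config <- function(master_seed = 1L, generator = list(),
                            preprocess = list(), network = list(),
                            split = list()) {
  base <- list(
    master_seed = as.integer(master_seed),
    generator = list(
      concentrations = default_concentrations(),
      n_per_group = 100L,
      dose = unclass(dose_response_params()),
      colors = unclass(color_model()),
      render = unclass(render_params())
    ),
    preprocess = unclass(preprocess_config()),
    network = list(hidden = 18L, learning_rate = 0.1, momentum = 0.1,
                   max_epochs = 1000L, target_mse = 0.07, init_scale = 0.5),
    split = list(train_fraction = 3 / 4, stratified = TRUE)
  )
  base$generator <- modify_list(base$generator, generator)
  base$preprocess <- modify_list(base$preprocess, preprocess)
  base$network <- modify_list(base$network, network)
  base$split <- modify_list(base$split, split)
  structure(base, class = "pipeline_config")
}

modify_list <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- modify_list(base[[nm]], override[[nm]])
    else base[nm] <- list(override[[nm]])   # single-bracket form keeps NULLs
  }
  base
}

derive_seed <- function(master_seed, offset) {
  as.integer((as.double(master_seed) + 65537 * offset) %% 2147483629)
}

#' Read and write pipeline configurations as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns the configuration;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(master_seed = raw$master_seed)
  for (sec in c("generator", "preprocess", "network", "split"))
    cfg[[sec]] <- modify_list(cfg[[sec]], raw[[sec]])
  cfg
}

config_dose <- function(config)
  do.call(dose_response_params, config$generator$dose)
config_colors <- function(config)
  do.call(color_model, lapply(config$generator$colors, unlist))
config_render <- function(config)
  do.call(render_params, lapply(config$generator$render, unlist))
config_preprocess <- function(config)
  do.call(preprocess_config, config$preprocess)

#' Generate the configured dataset to a directory
#'
#' Renders the configured design (default: 12 concentration levels at 100
#' images each) and writes PNGs plus `manifest.csv`. Reruns with the same
#' configuration produce byte-identical manifests and images.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory.
#' @return The manifest data frame, invisibly.
#' @export
generate_assay_images <- function(config, dir) {
  ds <- generate_dataset(config$generator$concentrations,
                         config$generator$n_per_group,
                         config_dose(config), config_colors(config),
                         config_render(config), config$master_seed)
  write_dataset(ds, dir)
}

# Streamed render -> preprocess -> moments over the configured design, one
# image in memory at a time; identical to feature_table(generate_dataset(...))
# because the per-image seeds come from the same derivation.
pipeline_feature_table <- function(config, concentrations = NULL,
                                   n_per_group = NULL,
                                   color_offset = c(0, 0, 0),
                                   master_seed = NULL) {
  gen <- config$generator
  if (is.null(concentrations)) concentrations <- unlist(gen$concentrations)
  if (is.null(n_per_group)) n_per_group <- gen$n_per_group
  if (is.null(master_seed)) master_seed <- config$master_seed
  dose <- config_dose(config)
  colors <- config_colors(config)
  render <- config_render(config)
  pre <- config_preprocess(config)

  n_total <- length(concentrations) * n_per_group
  feats <- matrix(NA_real_, n_total, 9,
                  dimnames = list(NULL, moment_names()))
  conc <- numeric(n_total)
  ok <- logical(n_total)
  failures <- character(0)
  i <- 0L
  for (g in seq_along(concentrations)) {
    for (rep in seq_len(n_per_group)) {
      i <- i + 1L
      conc[i] <- concentrations[g]
      seed_i <- image_seed(master_seed, g, rep)
      c_eff <- effective_dose(concentrations[g], render$conc_jitter_sd, seed_i)
      f <- aggregation_fraction(c_eff, dose)
      col <- pmin(pmax(solution_color(f, colors) + color_offset, 0), 255)
      img <- render_well_image(col, render, seed_i)
      res <- tryCatch(color_moments(preprocess_well(img, pre)),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("group %d replicate %d: %s",
                                        g, rep, conditionMessage(res)))
      } else {
        feats[i, ] <- res
        ok[i] <- TRUE
      }
    }
  }
  if (length(failures) > 0.05 * n_total)
    stop(sprintf("segmentation failed for %d/%d images:\n%s",
                 length(failures), n_total,
                 paste(utils::head(failures, 10), collapse = "\n")))
  for (msg in failures) warning(msg, call. = FALSE)
  cbind(data.frame(concentration_uM = conc[ok]),
        as.data.frame(feats[ok, , drop = FALSE]))
}

#' Calibrate the assay end to end
#'
#' Runs the full pipeline on the configured synthetic design: render every
#' well image, preprocess (median filter, Hough segmentation, Gaussian
#' smoothing, 50 x 50 crop), extract the nine color moments, split 3:1
#' stratified by concentration, train the 9-18-1 network, and evaluate the
#' fit on both splits.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `assay_calibration`: the fitted [bpann()] model,
#'   the feature table, the split indices, and `evaluation_report`s for the
#'   training and test sets.
#' @export
calibrate_assay <- function(config = pipeline_config()) {
  ft <- pipeline_feature_table(config)
  sp <- split_dataset(ft, split_spec(config$split$train_fraction,
                                     config$split$stratified,
                                     seed = derive_seed(config$master_seed, 11)))
  xcols <- moment_names()
  net <- config$network
  fit <- bpann(ft[sp$train, xcols], ft$concentration_uM[sp$train],
               hidden = net$hidden, learning_rate = net$learning_rate,
               momentum = net$momentum, max_epochs = net$max_epochs,
               target_mse = net$target_mse, init_scale = net$init_scale,
               seed = derive_seed(config$master_seed, 23))
  pred_train <- predict(fit, ft[sp$train, xcols])
  pred_test <- predict(fit, ft[sp$test, xcols])
  structure(list(
    model = fit,
    features = ft,
    split = sp,
    train_report = evaluate_predictions(pred_train,
                                        ft$concentration_uM[sp$train]),
    test_report = evaluate_predictions(pred_test,
                                       ft$concentration_uM[sp$test]),
    config = config
  ), class = "assay_calibration")
}

#' @export
print.assay_calibration <- function(x, ...) {
  cat("Assay calibration on", nrow(x$features), "images\n")
  cat(sprintf("Training stopped after %d epochs (final MSE %.4f uM^2)\n",
              length(x$model$trace), x$model$trace[length(x$model$trace)]))
  cat("Training set:\n"); print(x$train_report)
  cat("Test set:\n"); print(x$test_report)
  invisible(x)
}

#' Persist a calibration run to a directory
#'
#' Writes the artifacts of [calibrate_assay()]: `model.json` (the fitted
#' network, reloadable with [read_bpann()]), `trace.csv` (per-epoch training
#' MSE), `evaluation.csv` (train/test R2, MSE, slope, intercept), and
#' `features.csv` (the full feature table with split assignment). Reruns from
#' the same configuration reproduce these files byte for byte.
#'
#' @param cal an [calibrate_assay()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_calibration <- function(cal, dir) {
  stopifnot(inherits(cal, "assay_calibration"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bpann(cal$model, file.path(dir, "model.json"))
  write.csv(data.frame(epoch = seq_along(cal$model$trace),
                       mse_uM2 = cal$model$trace),
            file.path(dir, "trace.csv"), row.names = FALSE)
  ev <- do.call(rbind, lapply(list(train = cal$train_report,
                                   test = cal$test_report), function(r)
    data.frame(r2 = r$r2, mse = r$mse, slope = r$slope,
               intercept = r$intercept, n = r$n)))
  ev <- cbind(split = rownames(ev), ev)
  write.csv(ev, file.path(dir, "evaluation.csv"), row.names = FALSE)
  ft <- cal$features
  ft$split <- ifelse(seq_len(nrow(ft)) %in% cal$split$train, "train", "test")
  write.csv(ft, file.path(dir, "features.csv"), row.names = FALSE)
  invisible(dir)
}

#' Quantify unknown images with a fitted model
#'
#' Per-image preprocess, feature extraction and prediction. Failures (e.g.
#' segmentation) are recorded per row and do not abort the run.
#'
#' @param model a [bpann()] fit (or an [calibrate_assay()] result).
#' @param images list of [well_image()], or a directory of PNG files.
#' @param cfg a [preprocess_config()].
#' @return Data frame with columns `id`, `predicted_uM` (NA on failure),
#'   `error` (empty string when clean).
#' @export
quantify_images <- function(model, images, cfg = preprocess_config()) {
  if (inherits(model, "assay_calibration")) model <- model$model
  ids <- NULL
  if (is.character(images) && length(images) == 1 && dir.exists(images)) {
    files <- sort(list.files(images, pattern = "\\.png$", full.names = TRUE))
    ids <- basename(files)
    images <- lapply(files, function(f)
      tryCatch(read_well_png(f), error = function(e) e))
  }
  if (is.null(ids)) ids <- as.character(seq_along(images))
  out <- data.frame(id = ids,
                    predicted_uM = rep(NA_real_, length(ids)),
                    error = rep("", length(ids)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(images)) {
    res <- tryCatch({
      img <- images[[i]]
      if (inherits(img, "error")) stop(conditionMessage(img))
      predict(model, color_moments(preprocess_well(as_well_image(img), cfg)))
    }, error = function(e) e)
    if (inherits(res, "error")) out$error[i] <- conditionMessage(res)
    else out$predicted_uM[i] <- res
  }
  out
}

#' Assay limit of detection from a calibration
#'
#' Uses the pipeline-predicted concentrations of the zero-dose images as the
#' blank responses and the calibration's predicted-vs-true slope as the
#' sensitivity, then applies the IUPAC formula `k * sd(blank) / slope`.
#'
#' @param cal an [calibrate_assay()] result.
#' @param k blank-SD multiplier (3 classic, 3.3 supported).
#' @return An [lod_iupac()] result.
#' @export
assay_lod <- function(cal, k = 3) {
  stopifnot(inherits(cal, "assay_calibration"))
  blanks_idx <- which(cal$features$concentration_uM == 0)
  if (length(blanks_idx) < 3) stop("need at least three zero-dose images")
  blanks <- predict(cal$model, cal$features[blanks_idx, moment_names()])
  lod_iupac(blanks, slope = cal$train_report$slope, k = k)
}

#' Spike-recovery experiment on matrix-shifted synthetic images
#'
#' Emulates spiked real-matrix samples by adding a fixed RGB offset (the
#' matrix effect) to the rendered solution color at each spiked level,
#' quantifying the replicates with the calibrated model, and summarizing
#' recovery and RSD per level.
#'
#' @param cal an [calibrate_assay()] result.
#' @param spiked_levels spiked concentrations, uM (> 0).
#' @param n_replicates replicates per level (>= 2).
#' @param matrix_offset_rgb additive RGB offset emulating the sample matrix.
#' @param seed integer seed for the replicate renders.
#' @return Data frame with one [recovery_rsd()] row per spiked level.
#' @export
assay_recovery <- function(cal, spiked_levels = c(0.5, 1.5, 3.1),
                           n_replicates = 3, matrix_offset_rgb = c(3, 2, -2),
                           seed = 1L) {
  stopifnot(inherits(cal, "assay_calibration"), all(spiked_levels > 0),
            n_replicates >= 2)
  config <- cal$config
  rows <- vector("list", length(spiked_levels))
  for (j in seq_along(spiked_levels)) {
    ft <- pipeline_feature_table(config,
                                 concentrations = spiked_levels[j],
                                 n_per_group = n_replicates,
                                 color_offset = matrix_offset_rgb,
                                 master_seed = derive_seed(seed, 1000 + j))
    measured <- predict(cal$model, ft[, moment_names()])
    rows[[j]] <- recovery_rsd(spiked_levels[j], measured)
  }
  do.call(rbind, rows)
}
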