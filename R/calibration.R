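#' Train/test split specification
#'
#' @param train_fraction fraction of each group assigned to the training set
#'   (default 3/4, the assay's 3:1 split).
#' @param stratified split within each concentration group (default) or over
#'   the pooled samples.
#' @param seed integer seed for the random partition.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 3 / 4, stratified = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a feature table into training and test sets
#'
#' Seeded sampling without replacement; with stratification every
#' concentration group is partitioned `train_fraction : 1 - train_fraction`
#' separately, so each level appears in both sets. The returned index sets
#' partition the rows: their union is all rows, their intersection empty.
#'
#' @param x a feature data frame with a `concentration_uM` column, or a
#'   [generate_dataset()] result.
#' @param spec a [split_spec()].
#' @return List with integer row indices `train` and `test`.
#' @export
#' @examples
#' ft <- data.frame(concentration_uM = rep(c(0, 1), each = 8), m = rnorm(16))
#' sp <- split_dataset(ft, split_spec(seed = 3))
#' length(sp$train); length(sp$test)
split_dataset <- function(x, spec = split_spec()) {
  groups <- if (inherits(x, "synthetic_dataset")) {
    x$manifest$concentration_uM
  } else if (is.data.frame(x)) {
    if (!"concentration_uM" %in% names(x))
      stop("feature table lacks a concentration_uM column")
    x$concentration_uM
  } else stop("unsupported input type")
  n <- length(groups)
  if (n < 2) stop("need at least two samples to split")

  with_preserved_rng({
    set.seed(spec$seed)
    if (spec$stratified) {
      train <- integer(0)
      for (g in unique(groups)) {
        idx <- which(groups == g)
        if (length(idx) < 2)
          stop(sprintf("group %s has fewer than two members; cannot stratify",
                       format(g)))
        k <- round(spec$train_fraction * length(idx))
        k <- min(max(k, 1L), length(idx) - 1L)
        train <- c(train, sort(sample(idx, k)))
      }
      train <- sort(train)
    } else {
      k <- round(spec$train_fraction * n)
      k <- min(max(k, 1L), n - 1L)
      train <- sort(sample.int(n, k))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Evaluate predicted against true concentrations
#'
#' Computes the prediction mean squared error, the coefficient of
#' determination against the identity line (`R^2 = 1 - SS_res / SS_tot` with
#' residuals `pred - truth`), and the ordinary least-squares slope and
#' intercept of predicted on true values.
#'
#' @param pred,truth numeric vectors of equal nonzero length, uM.
#' @return A list of class `evaluation_report` with `r2`, `mse`, `slope`,
#'   `intercept`, `n`.
#' @export
#' @examples
#' evaluate_predictions(c(0.1, 1.1, 2.1), c(0, 1, 2))
evaluate_predictions <- function(pred, truth) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  if (length(pred) != length(truth) || length(pred) == 0)
    stop("pred and truth must have equal nonzero length")
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0)
    stop("truth has zero variance; r2 and slope are undefined")
  mse <- mean((pred - truth)^2)
  r2 <- 1 - sum((pred - truth)^2) / ss_tot
  slope <- sum((truth - mean(truth)) * (pred - mean(pred))) / ss_tot
  intercept <- mean(pred) - slope * mean(truth)
  structure(list(r2 = r2, mse = mse, slope = slope, intercept = intercept,
                 n = length(pred)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("  n = %d, R2 = %.4f, MSE = %.4f uM^2\n", x$n, x$r2, x$mse))
  cat(sprintf("  predicted = %.4f x true %+.4f\n", x$slope, x$intercept))
  invisible(x)
}

#' IUPAC limit of detection
#'
#' `LOD = k * sd(blank responses) / slope` with the sample standard deviation
#' (n - 1 denominator). By convention `k = 3` (the classic 3-sigma rule);
#' `k = 3.3` is also in common use and supported. Here the natural blank
#' response is the pipeline-predicted concentration of zero-dose images, in
#' which case the calibration slope is the predicted-vs-true slope.
#'
#' @param blank_responses at least three replicate blank measurements.
#' @param slope calibration sensitivity (response per uM), > 0.
#' @param k multiplier of the blank standard deviation.
#' @return A list of class `lod_result` with `lod` (uM), `blank_sd`, `slope`,
#'   `k_factor`.
#' @export
#' @examples
#' lod_iupac(c(0.02, -0.03, 0.08, 0.01), slope = 1)
lod_iupac <- function(blank_responses, slope, k = 3) {
  if (length(blank_responses) < 3)
    stop("need at least three blank replicates")
  if (!is.numeric(slope) || slope <= 0) stop("slope must be positive")
  s <- sd(blank_responses)
  structure(list(lod = k * s / slope, blank_sd = s, slope = slope,
                 k_factor = k),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("LOD = %.4f uM  (k = %g, blank SD = %.4g, slope = %.4g)\n",
              x$lod, x$k_factor, x$blank_sd, x$slope))
  invisible(x)
}

#' Spike recovery and relative standard deviation
#'
#' For a sample spiked at a known concentration and measured in replicate:
#' `recovery = 100 * mean(measured) / spiked`, and
#' `RSD = 100 * sd(measured) / mean(measured)` (sample standard deviation).
#'
#' @param spiked_conc spiked concentration, uM (> 0).
#' @param measured numeric vector of at least two replicate measurements, uM.
#' @return One-row data frame: `spiked_conc`, `measured_mean`, `recovery_pct`,
#'   `rsd_pct`, `n`.
#' @export
#' @examples
#' recovery_rsd(1.0, c(0.9, 1.0, 1.1))
recovery_rsd <- function(spiked_conc, measured) {
  if (!is.numeric(spiked_conc) || length(spiked_conc) != 1 || spiked_conc <= 0)
    stop("spiked_conc must be a single positive concentration")
  if (length(measured) < 2) stop("need at least two replicates")
  m <- mean(measured)
  if (m == 0) stop("zero mean measurement; RSD undefined")
  data.frame(spiked_conc = spiked_conc,
             measured_mean = m,
             recovery_pct = 100 * m / spiked_conc,
             rsd_pct = 100 * sd(measured) / m,
             n = length(measured))
}
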