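#' Color-moment feature vector
#'
#' Computes the nine-value color-moment descriptor of an RGB image: for each
#' channel, the first moment (mean intensity, overall lightness), the second
#' moment (root of the central second moment, color spread), and the third
#' moment (signed cube root of the central third moment, asymmetry of the
#' color distribution). Population (1/N) moments are used. Moments are taken
#' on raw `[0, 255]` intensities; any rescaling for modelling is left to the
#' regression step.
#'
#' @param img a [well_image()] (or bare H x W x 3 array).
#' @return Named numeric vector of length 9, ordered
#'   `m_r1, m_r2, m_r3, m_g1, m_g2, m_g3, m_b1, m_b2, m_b3`.
#' @export
#' @examples
#' img <- well_image(array(100, dim = c(50, 50, 3)))
#' color_moments(img)  # means 100, all central moments 0
color_moments <- function(img) {
  img <- as_well_image(img)
  out <- numeric(9)
  for (ch in 1:3) {
    p <- as.vector(img$pixels[, , ch])
    m1 <- mean(p)
    d <- p - m1
    m2 <- sqrt(mean(d^2))
    c3 <- mean(d^3)
    m3 <- sign(c3) * abs(c3)^(1 / 3)
    out[(ch - 1) * 3 + 1:3] <- c(m1, m2, m3)
  }
  names(out) <- moment_names()
  out
}

moment_names <- function() {
  paste0("m_", rep(c("r", "g", "b"), each = 3), rep(1:3, times = 3))
}

#' Feature table of a set of well images
#'
#' Runs [preprocess_well()] and [color_moments()] over a list of images (or a
#' [generate_dataset()] result) and assembles the features into a data frame
#' suitable for [bpann()]. Segmentation failures are reported and their rows
#' dropped; the run aborts if more than `max_fail_frac` of the images fail.
#'
#' @param images list of [well_image()] or a `synthetic_dataset`.
#' @param cfg a [preprocess_config()].
#' @param max_fail_frac abort threshold on the segmentation-failure fraction.
#' @return Data frame with `concentration_uM` (NA when unknown), the nine
#'   moment columns, and audit columns `cx`, `cy`, `r`, `score`.
#' @export
feature_table <- function(images, cfg = preprocess_config(),
                          max_fail_frac = 0.05) {
  if (inherits(images, "synthetic_dataset")) images <- images$images
  n <- length(images)
  rows <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    img <- as_well_image(images[[i]])
    res <- tryCatch({
      crop <- preprocess_well(img, cfg)
      det <- attr(crop, "detection")
      c(concentration_uM = img$true_conc, color_moments(crop),
        cx = det$cx, cy = det$cy, r = det$r, score = det$score)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("image %d: %s", i, conditionMessage(res)))
    } else {
      rows[[i]] <- res
    }
  }
  if (length(failures) > max_fail_frac * n)
    stop(sprintf("segmentation failed for %d/%d images:\n%s",
                 length(failures), n,
                 paste(utils::head(failures, 10), collapse = "\n")))
  for (msg in failures) warning(msg, call. = FALSE)
  out <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
  out
}
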