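#' Preprocessing configuration
#'
#' Parameters of the three-step preprocessing chain: median filtering, circle
#' Hough segmentation, Gaussian smoothing, and cropping to the square
#' inscribed in the detected circle, resampled to `crop_size` x `crop_size`.
#'
#' @param median_kernel odd median-filter kernel side, pixels (>= 3).
#' @param hough_radius_min,hough_radius_max circle search range, pixels.
#'   `NULL` means scale-free defaults of `0.25` and `0.45` times the shorter
#'   image side.
#' @param hough_vote_threshold minimum accumulator votes as a fraction of the
#'   ideal perimeter vote count for that radius.
#' @param gaussian_sigma Gaussian smoothing sigma, pixels (> 0).
#' @param crop_size output crop side, pixels.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(median_kernel = 5,
                              hough_radius_min = NULL,
                              hough_radius_max = NULL,
                              hough_vote_threshold = 0.35,
                              gaussian_sigma = 1.0,
                              crop_size = 50) {
  stopifnot(median_kernel >= 3, median_kernel %% 2 == 1,
            hough_vote_threshold > 0, hough_vote_threshold <= 1,
            gaussian_sigma > 0, crop_size >= 1)
  if (!is.null(hough_radius_min) && !is.null(hough_radius_max))
    stopifnot(hough_radius_min > 0, hough_radius_min < hough_radius_max)
  structure(list(median_kernel = as.integer(median_kernel),
                 hough_radius_min = hough_radius_min,
                 hough_radius_max = hough_radius_max,
                 hough_vote_threshold = hough_vote_threshold,
                 gaussian_sigma = gaussian_sigma,
                 crop_size = as.integer(crop_size)),
            class = "preprocess_config")
}

apply_channelwise <- function(img, fun) {
  img <- as_well_image(img)
  px <- img$pixels
  out <- array(0, dim = dim(px))
  for (ch in 1:3) out[, , ch] <- fun(px[, , ch])
  res <- img
  res$pixels <- out
  res
}

#' Median filter
#'
#' Channel-wise k x k median with reflect padding. Run before Hough detection
#' to suppress salt-and-pepper noise that would otherwise litter the edge map.
#'
#' @param img a [well_image()] (or bare H x W x 3 array).
#' @param kernel odd kernel side, >= 3 and <= the shorter image side.
#' @return Filtered `well_image` of the same shape.
#' @export
median_filter <- function(img, kernel = 5) {
  img <- as_well_image(img)
  d <- dim(img$pixels)
  if (kernel %% 2 != 1 || kernel < 3) stop("kernel must be odd and >= 3")
  if (kernel > min(d[1:2])) stop("kernel exceeds image size")
  apply_channelwise(img, function(m) cpp_median_filter(m, as.integer(kernel)))
}

#' Gaussian filter
#'
#' Channel-wise convolution with a normalized Gaussian truncated at +/- 3
#' sigma, reflect padding.
#'
#' @param img a [well_image()] (or bare array).
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return Smoothed `well_image` of the same shape.
#' @export
gaussian_filter <- function(img, sigma = 1.0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  apply_channelwise(img, function(m) cpp_gaussian_blur(m, sigma))
}

# Rec. 601 luma; inputs and output on the [0, 255] scale.
rgb_to_gray <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# Otsu threshold over a 256-bin histogram of non-negative values.
otsu_threshold <- function(x) {
  hi <- max(x)
  if (hi <= 0) return(0)
  breaks <- seq(0, hi, length.out = 257)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  breaks[which.max(between) + 1]
}

# Number of lattice offsets whose rounded distance equals r (ideal perimeter
# vote count for a full circle of radius r).
perimeter_votes <- function(r) {
  off <- -(r + 1):(r + 1)
  d <- round(sqrt(outer(off^2, off^2, "+")))
  sum(d == r)
}

#' Circle Hough detection of the solution region
#'
#' Converts to grayscale, median-prefilters, builds a Sobel gradient-magnitude
#' edge map thresholded by Otsu's method, then accumulates votes over all
#' candidate centers and radii in the configured range: a candidate
#' `(cx, cy, r)` receives one vote per edge pixel whose rounded distance from
#' the center equals `r`. The winner is the in-bounds candidate with maximal
#' votes; ties break toward larger radius, then smaller `(cy, cx)`.
#'
#' @param img a [well_image()].
#' @param cfg a [preprocess_config()].
#' @return A list of class `circle_detection` with fields `cx`, `cy`
#'   (0-based pixel coordinates, x = column, y = row), `r` (pixels), and
#'   `score` (accumulator votes).
#' @export
hough_detect_circle <- function(img, cfg = preprocess_config()) {
  img <- as_well_image(img)
  d <- dim(img$pixels)
  H <- d[1]; W <- d[2]
  rmin <- cfg$hough_radius_min
  rmax <- cfg$hough_radius_max
  if (is.null(rmin)) rmin <- max(3L, floor(0.25 * min(H, W)))
  if (is.null(rmax)) rmax <- ceiling(0.45 * min(H, W))
  rmin <- as.integer(rmin); rmax <- as.integer(rmax)
  if (min(H, W) < 2 * rmin) stop("image smaller than twice the minimum radius")

  gray <- cpp_median_filter(rgb_to_gray(img$pixels),
                            as.integer(cfg$median_kernel))
  mag <- cpp_sobel_magnitude(gray)
  # absolute floor guards against floating-point dust on (near-)constant images
  edge <- mag > max(otsu_threshold(mag), 1e-6)
  if (!any(edge))
    stop("segmentation failure: no edges found",
         if (!is.na(img$seed_tag)) paste0(" in image ", img$seed_tag) else "")

  votes <- cpp_hough_votes(edge, rmin, rmax)
  radii <- rmin:rmax
  perim <- vapply(radii, perimeter_votes, numeric(1))

  best <- NULL
  for (k in rev(seq_along(radii))) {      # larger radius wins ties
    r <- radii[k]
    if (W < 2 * r + 1 || H < 2 * r + 1) next
    slab <- votes[(r + 1):(H - r), (r + 1):(W - r), k, drop = FALSE]
    m <- max(slab)
    if (m < cfg$hough_vote_threshold * perim[k]) next
    if (!is.null(best) && m <= best$score) next
    hits <- which(slab == m, arr.ind = TRUE)
    # smaller (cy, cx) lexicographic among equals at this radius
    ord <- order(hits[, 1], hits[, 2])
    cy <- hits[ord[1], 1] + r - 1       # back to 0-based full-image coords
    cx <- hits[ord[1], 2] + r - 1
    best <- list(cx = as.numeric(cx), cy = as.numeric(cy),
                 r = as.numeric(r), score = as.numeric(m))
  }
  if (is.null(best))
    stop("segmentation failure: no circle reached the vote threshold",
         if (!is.na(img$seed_tag)) paste0(" in image ", img$seed_tag) else "")
  structure(best, class = "circle_detection")
}

#' @export
print.circle_detection <- function(x, ...) {
  cat(sprintf("<circle_detection: center (%.1f, %.1f), r = %.1f px, %d votes>\n",
              x$cx, x$cy, x$r, as.integer(x$score)))
  invisible(x)
}

# Bilinear sample of one channel at fractional (x, y), 0-based, clamped.
bilinear_sample <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  x <- pmin(pmax(x, 0), W - 1)
  y <- pmin(pmax(y, 0), H - 1)
  x0 <- pmin(floor(x), W - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), H - 2); y1 <- y0 + 1
  if (W == 1) { x0 <- x1 <- 0 }
  if (H == 1) { y0 <- y1 <- 0 }
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  (1 - fy) * ((1 - fx) * m[i00] + fx * m[i01]) +
    fy * ((1 - fx) * m[i10] + fx * m[i11])
}

#' Crop to the square inscribed in the detected circle
#'
#' Extracts the axis-aligned square of side `sqrt(2) * r` centered on the
#' detection and resamples it to `size` x `size` by bilinear interpolation.
#' Because the square is inscribed in the circle, a correct detection yields a
#' crop containing only solution pixels.
#'
#' @param img a [well_image()].
#' @param det a [hough_detect_circle()] result.
#' @param size output side, pixels.
#' @return A `size` x `size` x 3 `well_image`.
#' @export
crop_to_square <- function(img, det, size = 50) {
  img <- as_well_image(img)
  d <- dim(img$pixels)
  side <- det$r * sqrt(2)
  x0 <- det$cx - side / 2
  y0 <- det$cy - side / 2
  if (x0 < -0.5 || y0 < -0.5 ||
      x0 + side > d[2] - 0.5 || y0 + side > d[1] - 0.5)
    stop("inscribed square exceeds image bounds (bad detection?)")
  # target pixel centers mapped into source coordinates; when size == side and
  # the square is grid-aligned this reduces to identity sampling
  tx <- x0 + (seq_len(size) - 0.5) * side / size - 0.5
  ty <- y0 + (seq_len(size) - 0.5) * side / size - 0.5
  gx <- rep(tx, each = size)
  gy <- rep(ty, times = size)
  out <- array(0, dim = c(size, size, 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(img$pixels[, , ch], gx, gy),
                          size, size)
  res <- img
  res$pixels <- pmin(pmax(out, 0), 255)
  res
}

#' Full preprocessing chain
#'
#' Median filter, circle Hough segmentation, Gaussian smoothing, and crop to
#' the inscribed square resampled to `crop_size` x `crop_size`, in that order.
#' Deterministic: repeated runs on the same image give identical output.
#'
#' @param img a [well_image()].
#' @param cfg a [preprocess_config()].
#' @return The cropped `well_image` with the [hough_detect_circle()] result
#'   attached as attribute `"detection"` for audit logging.
#' @export
#' @examples
#' img <- render_well_image(c(180, 70, 130), render_params(), seed = 3)
#' out <- preprocess_well(img)
#' dim(out$pixels)
preprocess_well <- function(img, cfg = preprocess_config()) {
  img <- as_well_image(img)
  med <- median_filter(img, cfg$median_kernel)
  det <- hough_detect_circle(med, cfg)
  smooth <- gaussian_filter(med, cfg$gaussian_sigma)
  out <- crop_to_square(smooth, det, cfg$crop_size)
  attr(out, "detection") <- det
  out
}
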