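#' Well image container
#'
#' A `well_image` wraps an H x W x 3 raster of 8-bit RGB intensities (stored
#' as numeric in `[0, 255]`, channel order fixed as R, G, B) together with an
#' optional known amoxicillin concentration and a provenance tag. It is the
#' raw input to the preprocessing pipeline and the output of the synthetic
#' generator.
#'
#' @param pixels numeric H x W x 3 array with values in `[0, 255]`.
#' @param true_conc known concentration in uM, or `NA` if unknown.
#' @param seed_tag character provenance identifier (e.g. the render seed).
#' @return An object of class `well_image`.
#' @export
#' @examples
#' img <- well_image(array(128, dim = c(60, 60, 3)))
#' dim(img$pixels)
well_image <- function(pixels, true_conc = NA_real_, seed_tag = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must contain at least one pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels, true_conc = as.numeric(true_conc),
         seed_tag = as.character(seed_tag)),
    class = "well_image"
  )
}

#' @export
print.well_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<well_image %d x %d x 3", d[1], d[2]))
  if (!is.na(x$true_conc)) cat(sprintf(", %.3g uM", x$true_conc))
  if (!is.na(x$seed_tag)) cat(sprintf(", seed %s", x$seed_tag))
  cat(">\n")
  invisible(x)
}

as_well_image <- function(x) {
  if (inherits(x, "well_image")) return(x)
  well_image(x)
}

#' Read and write well images as PNG
#'
#' Images are stored as ordinary 8-bit RGB PNG files. On read, intensities are
#' rescaled from `[0, 1]` to `[0, 255]`; grayscale and RGBA rasters are
#' promoted/truncated to three channels.
#'
#' @param path file path.
#' @param img a [well_image()].
#' @return `read_well_png` returns a `well_image`; `write_well_png` returns
#'   `path` invisibly.
#' @export
read_well_png <- function(path) {
  raster <- png::readPNG(path)
  if (length(dim(raster)) == 2L)
    raster <- array(rep(raster, 3L), dim = c(dim(raster), 3L))
  if (dim(raster)[3] > 3L) raster <- raster[, , 1:3, drop = FALSE]
  well_image(round(raster * 255), seed_tag = basename(path))
}

#' @rdname read_well_png
#' @export
write_well_png <- function(img, path) {
  img <- as_well_image(img)
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
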