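#' Raster image container
#'
#' A minimal container for a 3-channel raster image together with the color
#' space its values live in. Pixel values are doubles; sRGB images are
#' expected in \[0, 1\], CIELab images carry L* in \[0, 100\] (for valid sRGB
#' input) and signed a*, b* chroma channels.
#'
#' @param pixels numeric array of dimension height x width x 3.
#' @param color_space either `"sRGB"` or `"CIELab"`.
#' @return an object of class `raster_image` with fields `pixels` and
#'   `color_space`.
#' @export
raster_image <- function(pixels, color_space = c("sRGB", "CIELab")) {
  color_space <- match.arg(color_space)
  pixels <- as.array(pixels)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stopf("pixels must be a height x width x 3 array, got dims [%s]",
          paste(d, collapse = ", "))
  if (d[1] < 1L || d[2] < 1L) stopf("image must have height, width >= 1")
  if (!all(is.finite(pixels))) stopf("pixel values must be finite")
  if (color_space == "sRGB" && (min(pixels) < 0 || max(pixels) > 1))
    stopf("sRGB values must lie in [0, 1]; range is [%g, %g]",
          min(pixels), max(pixels))
  structure(list(pixels = pixels, color_space = color_space),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %d x %d, %s>\n", d[1], d[2], x$color_space))
  invisible(x)
}

#' @noRd
image_dims <- function(img) dim(img$pixels)[1:2]

#' Convert an sRGB image to CIE L*a*b*
#'
#' Uses the standard sRGB transfer curve and the D65 white point, the de
#' facto interpretation for uncalibrated consumer imagery such as dermoscopy
#' atlas photographs. L* lands in \[0, 100\] for valid input.
#'
#' @param img a [raster_image] in sRGB with values in \[0, 1\].
#' @return a [raster_image] in CIELab.
#' @export
rgb_to_lab <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$color_space != "sRGB") stopf("rgb_to_lab expects an sRGB image")
  px <- img$pixels
  if (min(px) < 0 || max(px) > 1)
    stopf("sRGB values outside [0, 1]: range [%g, %g]", min(px), max(px))
  d <- dim(px)
  flat <- matrix(px, ncol = 3L)   # column-major flattening; restored below
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  raster_image(array(lab, dim = d), color_space = "CIELab")
}

#' Convert a CIE L*a*b* image back to sRGB
#'
#' Inverse of [rgb_to_lab()] (D65, standard sRGB gamma). Out-of-gamut values
#' are clipped to \[0, 1\]. Used by the synthetic-data generator to apply
#' exposure offsets in L*.
#'
#' @param img a [raster_image] in CIELab.
#' @return a [raster_image] in sRGB.
#' @export
lab_to_rgb <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$color_space != "CIELab") stopf("lab_to_rgb expects a CIELab image")
  d <- dim(img$pixels)
  flat <- matrix(img$pixels, ncol = 3L)
  rgb <- grDevices::convertColor(flat, from = "Lab", to = "sRGB")
  rgb <- pmin(pmax(rgb, 0), 1)
  raster_image(array(rgb, dim = d), color_space = "sRGB")
}

#' Normalize the L* channel to zero mean
#'
#' Subtracts the image-wide mean of the L* channel, leaving a* and b*
#' untouched. Differences in global camera exposure shift L* by a constant,
#' so this removes exposure variation between images acquired with differing
#' equipment. Idempotent.
#'
#' @param img a [raster_image] in CIELab.
#' @return a [raster_image] in CIELab with `mean(L*) == 0`.
#' @export
normalize_lstar <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$color_space != "CIELab")
    stopf("normalize_lstar expects a CIELab image")
  px <- img$pixels
  px[, , 1] <- px[, , 1] - mean(px[, , 1])
  structure(list(pixels = px, color_space = "CIELab"),
            class = "raster_image")
}

#' Read an sRGB image from a PNG file
#'
#' 8- or 16-bit PNGs are mapped to \[0, 1\] doubles; grayscale images are
#' replicated to 3 channels, alpha is dropped.
#'
#' @param path file path.
#' @return a [raster_image] in sRGB.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  raster_image(px, color_space = "sRGB")
}

#' Write an sRGB image to a PNG file
#'
#' @param img a [raster_image] in sRGB.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  if (img$color_space != "sRGB") stopf("write_image_png expects sRGB")
  png::writePNG(img$pixels, path)
  invisible(path)
}
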