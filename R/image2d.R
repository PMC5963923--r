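#' 2D grayscale image with a physical scale
#'
#' Light container for a single-channel raster: a numeric matrix of
#' non-negative intensities plus the pixel size in micrometres.  Rows run
#' downward (row 1 is the top of the image) and orientations are measured
#' counter-clockwise from the image horizontal axis on the axial range
#' \eqn{[0, 180)} degrees, so 0 is horizontal and 90 vertical.
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param scale pixel size in micrometres per pixel; must be positive.
#' @return An object of class `image2d`: a list with elements `pixels`
#'   and `scale`.
#' @examples
#' img <- image2d(matrix(runif(64), 8, 8), scale = 0.5)
#' dim(img)
#' @export
image2d <- function(pixels, scale) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("`pixels` must be a numeric matrix")
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stopf("`scale` must be a single positive number (micrometres/pixel)")
  }
  structure(list(pixels = pixels, scale = as.numeric(scale)),
            class = "image2d")
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' @export
print.image2d <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image2d> %d x %d px @ %.4g um/px (%.5g x %.5g um)\n",
              d[1], d[2], x$scale, d[1] * x$scale, d[2] * x$scale))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.image2d <- function(x, ...) {
  # transpose + flip so the displayed orientation matches the row-down raster
  graphics::image(t(x$pixels[nrow(x$pixels):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1),
                  asp = nrow(x$pixels) / ncol(x$pixels),
                  axes = FALSE, ...)
  invisible(x)
}

#' Maximal-intensity projection of an image stack
#'
#' Collapses an ordered list of slices (e.g. a confocal Z-stack) into a
#' single image by taking the per-pixel maximum, the standard projection
#' for visualizing cell walls and fibrillar signal.
#'
#' @param stack a non-empty list of [image2d] objects sharing dimensions
#'   and scale.
#' @return An [image2d] with the per-pixel maximum.
#' @examples
#' a <- image2d(matrix(0, 4, 4), 1)
#' b <- image2d(matrix(runif(16), 4, 4), 1)
#' identical(max_project(list(a, b))$pixels, b$pixels)
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L) {
    stopf("`stack` must be a non-empty list of image2d slices")
  }
  if (!all(vapply(stack, inherits, logical(1), "image2d"))) {
    stopf("all slices must be image2d objects")
  }
  d <- dim(stack[[1L]]$pixels)
  sc <- stack[[1L]]$scale
  for (s in stack) {
    if (!identical(dim(s$pixels), d)) stopf("slices differ in shape")
    if (!isTRUE(all.equal(s$scale, sc))) stopf("slices differ in scale")
  }
  out <- stack[[1L]]$pixels
  for (s in stack[-1L]) out <- pmax(out, s$pixels)
  image2d(out, sc)
}

#' Read a grayscale image from TIFF or PNG
#'
#' Reads an 8/16-bit grayscale TIFF or PNG.  Multi-channel input requires
#' an explicit `channel`; the physical scale must be supplied (or present
#' in a JSON sidecar written by [write_image]) -- it is never assumed.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param scale micrometres per pixel.  If `NULL`, a sidecar
#'   `<path>.json` with a `scale_um_per_px` entry is consulted; missing
#'   scale is an error.
#' @param channel channel index for multi-channel images (error if the
#'   image has several channels and `channel` is `NULL`).
#' @return An [image2d].
#' @export
read_image <- function(path, scale = NULL, channel = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stopf("unsupported image extension '.%s' (use TIFF or PNG)", ext)
  )
  if (length(dim(arr)) == 3L) {
    if (is.null(channel)) {
      stopf("image has %d channels; supply `channel`", dim(arr)[3])
    }
    arr <- arr[, , channel]
  }
  if (is.null(scale)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      scale <- meta$scale_um_per_px
    }
  }
  if (is.null(scale)) {
    stopf("no scale given and no sidecar found for '%s'; a um/px scale is required",
          path)
  }
  image2d(arr, scale)
}

#' Write a grayscale image to 16-bit TIFF or PNG with a scale sidecar
#'
#' Intensities are clipped to \[0, 1\] on write.  The micrometre scale is
#' recorded in a JSON sidecar `<path>.json` so that [read_image] can
#' round-trip the physical calibration.
#'
#' @param img an [image2d].
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  px <- pmin(pmax(img$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    stopf("unsupported image extension '.%s' (use TIFF or PNG)", ext)
  )
  jsonlite::write_json(list(scale_um_per_px = img$scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
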