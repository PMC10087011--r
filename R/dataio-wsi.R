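#' Read a whole-slide H&E image (flat TIFF or PNG)
#'
#' Loads an RGB image with its physical pixel size. No resampling is done.
#' 16-bit TIFF input is rescaled to 8-bit with a warning; grayscale input is
#' rejected; an alpha channel is dropped with a warning. Pyramidal WSI
#' formats are out of scope: export a flat image first.
#'
#' @param path path to a \file{.png}, \file{.tif} or \file{.tiff} file
#' @param pixel_size_um physical edge length of one image pixel, micrometers
#' @return a \code{WSImage}: a list with elements \code{image} (rows x cols x
#'   3 array, values in [0, 1]) and \code{pixel_size_um}.
#' @export
readWSI <- function(path, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar", call. = FALSE)
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits > 8L) {
      warning("16-bit TIFF rescaled to 8-bit")
      img <- round(img * 255) / 255
    }
    attributes(img) <- list(dim = dim(img))
  } else {
    stop("unsupported image format: .", ext, " (use flat TIFF or PNG)",
         call. = FALSE)
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("whole-slide image must have 3 colour channels (got ",
         if (length(dim(img)) == 2L) "grayscale" else dim(img)[3], ")",
         call. = FALSE)
  if (dim(img)[3] > 3L) {
    warning("alpha channel dropped")
    img <- img[, , 1:3, drop = FALSE]
  }
  structure(list(image = img, pixel_size_um = pixel_size_um),
            class = "WSImage")
}

#' @export
print.WSImage <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("WSImage: %d x %d px RGB at %.4g um/px\n", d[1], d[2],
              x$pixel_size_um))
  invisible(x)
}

#' Write an RGB array or WSImage to PNG (lossless)
#'
#' @param image a \code{WSImage} or a rows x cols x 3 array in [0, 1]
#' @param path output PNG path
#' @return invisibly, \code{path}
#' @export
writeWSI <- function(image, path) {
  if (inherits(image, "WSImage")) image <- image$image
  png::writePNG(image, path)
  invisible(path)
}
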