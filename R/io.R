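#' Read a disc image as an (H, W, 3) array
#'
#' Reads a JPG/PNG/TIFF image and returns a numeric array in this package's
#' internal convention: dimensions `(height, width, 3)`, RGB values in
#' 0..255, y growing downward. Grayscale images are expanded to three
#' identical channels.
#'
#' @param path Image file path.
#' @return Numeric `(H, W, 3)` array, values in 0..255.
#' @export
read_disc_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {
    dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  } else if (dim(dat)[3] > 3L) {
    dat <- dat[, , 1:3, drop = FALSE] # drop alpha
  }
  out <- aperm(dat, c(2, 1, 3)) * 255
  dimnames(out) <- NULL
  out
}

#' Write an (H, W, 3) array as an image file
#'
#' @param image Numeric `(H, W, 3)` array with values in 0..255.
#' @param path Output path; format from extension (.jpg/.png/.tif).
#' @param quality JPEG quality (ignored for other formats).
#' @return Invisibly, `path`.
#' @export
write_disc_image <- function(image, path, quality = 95) {
  check_image_array(image)
  dat <- aperm(pmin(pmax(image / 255, 0), 1), c(2, 1, 3))
  img <- EBImage::Image(dat, colormode = "Color")
  EBImage::writeImage(img, path, quality = quality)
  invisible(path)
}
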