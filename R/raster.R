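# PNG-backed raster I/O. Images are h x w x 3 arrays in [0, 1]; masks are
# logical matrices written as single-channel 0/255 PNG.

#' Write an RGB image as PNG
#' @param image Numeric array h x w x 3 with values in \[0, 1\].
#' @param path Output file path.
#' @export
write_image_png <- function(image, path) {
  ot_assert(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3,
            "image must be an h x w x 3 array")
  png::writePNG(clamp(image, 0, 1), target = path)
  invisible(path)
}

#' Read an RGB image from PNG
#' @param path PNG file path.
#' @return Numeric array h x w x 3 in \[0, 1\].
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a binary mask as a 0/255 single-channel PNG
#' @param mask Logical matrix.
#' @param path Output file path.
#' @export
write_mask_png <- function(mask, path) {
  ot_assert(is.matrix(mask), "mask must be a matrix")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG file path.
#' @return Logical matrix (pixel > 0.5).
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
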