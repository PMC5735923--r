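# Standardization: greyscale conversion, geometry adjustment to 640x480,
# percentile contrast stretch. All downstream stages consume the result.

#' Convert an image to 8-bit greyscale
#'
#' RGB images are converted with ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114) and rounded half-up; greyscale inputs pass through
#' unchanged.
#'
#' @param img canonical pixel array (matrix or h x w x 3 array, 0..255).
#' @return integer matrix, 0..255.
#' @export
to_greyscale <- function(img) {
  if (length(dim(img)) == 2) return(img)
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  floor(g + 0.5)  # round half-up, not banker's rounding
}

#' Adjust image geometry to 640x480
#'
#' Forces the 0.75 height/width proportion and resizes to 640x480. Images
#' taller than the 0.75 proportion are cropped from the top (a 1280x1024
#' frame loses exactly 64 top rows); wider images are cropped symmetrically
#' from the left and right. Resizing is bilinear with anti-aliasing and is
#' skipped when the cropped image is already 640x480.
#'
#' @param img greyscale matrix (0..255).
#' @return integer matrix, exactly 480 x 640.
#' @export
adjust_geometry <- function(img) {
  stopifnot(length(dim(img)) == 2)
  h <- nrow(img); w <- ncol(img)
  if (h < 8 || w < 8)
    bq_stop("bq_input_error", paste0("degenerate image (", w, "x", h, ")"))
  ratio <- h / w
  if (ratio > 0.75) {
    new_h <- round(0.75 * w)
    img <- img[(h - new_h + 1):h, , drop = FALSE]      # cut top rows
  } else if (ratio < 0.75) {
    new_w <- round(h / 0.75)
    excess <- w - new_w
    left <- excess %/% 2
    img <- img[, (left + 1):(left + new_w), drop = FALSE]  # symmetric cut
  }
  if (nrow(img) == 480 && ncol(img) == 640) return(img)
  e <- EBImage::resize(as_ebi(img), w = 640, h = 480, antialias = TRUE)
  from_ebi(e)
}

#' Percentile contrast stretch
#'
#' Linear contrast stretch saturating a fixed fraction of pixels at each
#' tail of the histogram (default 1% at each end): the lower-tail quantile
#' maps to 0 and the upper-tail quantile to 255, with clipping outside.
#' Constant images are returned unchanged with a warning.
#'
#' @param img greyscale matrix (0..255).
#' @param tails length-2 fraction of pixels saturated at the (low, high) end.
#' @return integer matrix of the same size, 0..255.
#' @export
stretch_intensity <- function(img, tails = c(0.01, 0.01)) {
  stopifnot(length(dim(img)) == 2)
  x <- as.numeric(img)
  lo <- quantile(x, tails[1], type = 1, names = FALSE)
  hi <- quantile(x, 1 - tails[2], type = 1, names = FALSE)
  if (hi <= lo) {
    warning("constant (or near-constant) image: no contrast stretch applied")
    return(img)
  }
  y <- (img - lo) * 255 / (hi - lo)
  round(pmin(pmax(y, 0), 255))
}

#' Standardize a micrograph
#'
#' Full standardization: import (if given a path), greyscale conversion,
#' geometry adjustment to 640x480, and percentile contrast stretch. Every
#' downstream stage of the pipeline consumes its output.
#'
#' @param x file path or canonical pixel array.
#' @param config a [pipeline_config()] list.
#' @return integer matrix, exactly 480 x 640, 0..255.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1))
#' std <- standardize_image(ph$image)
#' dim(std)
standardize_image <- function(x, config = pipeline_config()) {
  img <- if (is.character(x)) load_image(x) else x
  img <- to_greyscale(img)
  img <- adjust_geometry(img)
  stretch_intensity(img, tails = config$stretch_tails)
}
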