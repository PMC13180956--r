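#' Median filtering of an integer-intensity image
#'
#' Applies a square median filter independently to each channel, the
#' standard non-linear denoiser for impulse (salt-and-pepper) and shadow
#' noise: each pixel is replaced by the median of the `window` x `window`
#' neighbourhood centred on it. Borders are handled by symmetric
#' reflection, so output dimensions equal input dimensions and no value
#' can appear that was absent from the corresponding input window.
#'
#' @param image An `H x W x C` array (or `H x W` matrix) of intensities in
#'   `[0, 255]`; `C` must be 1 or 3.
#' @param window Odd positive integer side of the square window. Default 3.
#' @return An array of the same dimensions as `image`.
#' @examples
#' img <- array(0, c(5, 5, 1)); img[3, 3, 1] <- 255
#' max(median_filter(img, 3)) # the isolated spike is removed
#' @export
median_filter <- function(image, window = 3L) {
  image <- validate_raw_image(image)
  if (length(window) != 1L || !is.finite(window) || window < 1 ||
      window != as.integer(window) || as.integer(window) %% 2L == 0L)
    abort_invalid_parameter("`window` must be an odd positive integer.")
  window <- as.integer(window)
  if (window == 1L) return(image)
  d <- dim(image)
  out <- cpp_median_filter(as.numeric(image), d[1], d[2], d[3], window)
  dim(out) <- d
  out
}

#' Min-max intensity normalization
#'
#' Rescales an image to the unit interval with the affine map
#' \eqn{X' = (X - X_{min}) / (X_{max} - X_{min})}, where the minimum and
#' maximum are taken over the whole image (all channels jointly), so the
#' transform is per-image and stateless. A constant image maps to all
#' zeros rather than raising an error.
#'
#' @param image An `H x W x C` array (or matrix) of finite intensities.
#' @return An array of the same dimensions with values in `[0, 1]`.
#' @examples
#' min_max_normalize(matrix(c(0, 51, 255), 1))
#' @export
min_max_normalize <- function(image) {
  image <- as_image_array(image)
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) return(array(0, dim(image)))
  (image - lo) / (hi - lo)
}

#' Preprocess one image for the classifier
#'
#' The full cleaning pipeline applied before the network: median filtering
#' on the integer image followed by per-image min-max normalization.
#'
#' @inheritParams median_filter
#' @return A normalized array with values in `[0, 1]`.
#' @export
preprocess_image <- function(image, window = 3L) {
  min_max_normalize(median_filter(image, window))
}

#' Read a leaf image from disk
#'
#' Reads a PNG or JPEG file, converts it to 3-channel RGB (grayscale is
#' replicated, alpha dropped), and returns integer intensities in
#' `[0, 255]` with row-major, origin top-left orientation.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An `H x W x 3` array of integers in `[0, 255]`.
#' @export
read_leaf_image <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        abort_io("the 'jpeg' package is required to read JPEG files.")
      jpeg::readJPEG(path)
    },
    abort_io(sprintf("unsupported image format: .%s", ext))
  )
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] == 1L) x <- x[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(x)[3] >= 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}
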