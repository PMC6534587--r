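#' G-value image container
#'
#' A 2D grid of per-pixel G-values (green-channel intensity, 0-255) with an
#' optional exclusion mask used for anatomical structures that must not
#' enter the statistics (e.g. the half-moon structure of the rat tongue).
#' Pixel indexing is 0-based with origin at the top-left corner; rows are y,
#' columns are x.
#'
#' @param pixels numeric matrix of G-values in `[0, 255]` (full precision
#'   allowed; loaded 8-bit images are integer-valued).
#' @param mask logical matrix of the same dimensions; `TRUE` = excluded.
#'   Defaults to no exclusions.
#' @return an object of class `gvalue_image`.
#' @export
gvalue_image <- function(pixels, mask = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  }
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!identical(dim(pixels), dim(mask))) {
    stop("pixels and mask must have identical dimensions")
  }
  vals <- pixels[!mask]
  if (length(vals) && (min(vals) < 0 || max(vals) > 255)) {
    stop("unmasked G-values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, mask = mask), class = "gvalue_image")
}

#' @export
print.gvalue_image <- function(x, ...) {
  cat(sprintf(
    "<gvalue_image> %d x %d px, %d masked, G in [%.1f, %.1f]\n",
    nrow(x$pixels), ncol(x$pixels), sum(x$mask),
    min(x$pixels[!x$mask]), max(x$pixels[!x$mask])
  ))
  invisible(x)
}

#' @export
dim.gvalue_image <- function(x) dim(x$pixels)

#' Load a fluorescence image as G-values
#'
#' Reads an 8-bit RGB PNG or TIFF and returns the green channel verbatim as
#' G-values (0-255). An optional companion mask image (single channel;
#' non-zero = excluded) marks pixels to drop from all downstream statistics.
#'
#' @param path path to an 8-bit RGB PNG or TIFF file.
#' @param mask_path optional path to a mask image of the same size.
#' @return a [gvalue_image()].
#' @export
load_gvalue_image <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  arr <- read_image_array(path)
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L) {
    stop("expected an RGB image (3 channels): ", path)
  }
  g <- round(arr[, , 2L] * 255)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_image_array(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    if (!identical(dim(m), dim(g))) stop("mask dimensions do not match image")
    mask <- m > 0
  }
  gvalue_image(g, mask)
}

read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L) {
      stop("unsupported bit depth ", info$bit.depth, " (need 8-bit): ", path)
    }
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && bits != 8L) {
      stop("unsupported bit depth ", bits, " (need 8-bit): ", path)
    }
  } else {
    stop("unsupported image format: .", ext, " (use png or tiff)")
  }
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  arr
}
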