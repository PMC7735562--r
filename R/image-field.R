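#' @importFrom tiff readTIFF writeTIFF
NULL

FIELD_CHANNELS <- c("GFP", "HOECHST", "FILIPIN", "MARKER")

#' Construct a field image
#'
#' An `image_field` is one grayscale microscope field: a matrix of
#' intensities in `[0,1]` (row = image row, 0-based pixel coordinates are
#' `(row, col)`), a channel label, and the source path if the image came
#' from disk.  Fields smaller than 64 x 64 are rejected.
#'
#' @param pixels Numeric matrix with all values finite and in `[0,1]`.
#' @param channel One of `"GFP"`, `"HOECHST"`, `"FILIPIN"`, `"MARKER"`.
#' @param source_path Optional provenance string.
#' @return An object of class `image_field`.
#' @export
image_field <- function(pixels, channel, source_path = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("image_field: 'pixels' must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop("image_field: image must be at least 64 x 64 pixels, got ",
         nrow(pixels), " x ", ncol(pixels), call. = FALSE)
  if (anyNA(pixels) || !all(is.finite(pixels)))
    stop("image_field: intensities must all be finite", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1)
    stop("image_field: intensities must lie in [0,1]", call. = FALSE)
  channel <- match.arg(channel, FIELD_CHANNELS)
  structure(list(pixels = pixels, height = nrow(pixels),
                 width = ncol(pixels), channel = channel,
                 source_path = source_path),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field %s %d x %d, range [%.3f, %.3f]>\n",
              x$channel, x$height, x$width,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# accept either an image_field or a bare matrix; enforce channel if asked
field_pixels <- function(img, channel = NULL, what = "image") {
  if (inherits(img, "image_field")) {
    if (!is.null(channel) && img$channel != channel)
      stop(what, ": expected channel ", channel, ", got ", img$channel,
           call. = FALSE)
    img$pixels
  } else if (is.matrix(img) && is.numeric(img)) {
    img
  } else {
    stop(what, ": expected an image_field or numeric matrix", call. = FALSE)
  }
}

#' Read a grayscale field image from TIFF
#'
#' Reads a single-plane 8- or 16-bit grayscale TIFF and normalizes the
#' intensities by the dtype maximum (255 or 65535) so that the result
#' lies in `[0,1]`.  Normalization by the dtype maximum (not the
#' per-image maximum) keeps intensity features comparable across wells.
#'
#' @param path Path to the TIFF file.
#' @param channel Channel label recorded on the result.
#' @return An [image_field()].
#' @export
read_field_image <- function(path, channel) {
  channel <- match.arg(channel, FIELD_CHANNELS)
  if (!file.exists(path))
    stop("cannot read image, file not found: ", path, call. = FALSE)
  px <- tryCatch(tiff::readTIFF(path, all = FALSE),
                 error = function(e)
                   stop("failed to read TIFF '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (!is.matrix(px))
    stop("not a single-plane grayscale TIFF: ", path,
         " (multi-channel/RGB images are not supported)", call. = FALSE)
  # readTIFF already divides by the dtype maximum of the stored bit depth
  image_field(px, channel, source_path = path)
}

#' Write a field image as a 16-bit grayscale TIFF
#'
#' @param img An [image_field()] or a numeric matrix in `[0,1]`.
#' @param path Output path.
#' @param bits_per_sample 8 or 16.
#' @return Invisibly, `path`.
#' @export
write_field_image <- function(img, path, bits_per_sample = 16) {
  px <- field_pixels(img, what = "write_field_image")
  stopifnot(bits_per_sample %in% c(8, 16))
  # quantize explicitly so that a write/read round trip is exact
  mx <- 2^bits_per_sample - 1
  q <- round(px * mx) / mx
  tiff::writeTIFF(q, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}
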