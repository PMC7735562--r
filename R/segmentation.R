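#' Adaptive local-mean thresholding
#'
#' A pixel is foreground iff its value strictly exceeds the mean over a
#' `window_px` x `window_px` square centred on it (replicate-padded at
#' the borders) plus `offset`.  `window_px` is the full window width;
#' a constant image therefore yields an all-background mask for any
#' `offset >= 0`.
#'
#' @param img An [image_field()] or numeric matrix.
#' @param window_px Odd integer >= 3, full width of the local-mean
#'   window.
#' @param offset Additive offset.
#' @return Logical matrix (the foreground mask).
#' @export
adaptive_threshold <- function(img, window_px = 25, offset = 0.02) {
  x <- field_pixels(img, what = "adaptive_threshold")
  if (window_px < 3 || window_px %% 2 == 0)
    stop("adaptive_threshold: 'window_px' must be odd and >= 3",
         call. = FALSE)
  box <- matrix(1 / window_px^2, window_px, window_px)
  loc <- as.matrix(EBImage::filter2(x, box, boundary = "replicate"))
  # the FFT-based local mean carries ~1e-16 roundoff; guard the strict
  # inequality so exact ties (constant regions at offset 0) stay
  # background
  (x - loc) > (offset + 1e-10)
}

# Gaussian blur with replicate padding when the image is smaller than
# the blur kernel (EBImage::gblur refuses filters larger than the
# image); full-size fields take the direct path.
gaussian_blur <- function(x, sigma) {
  brush <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  ph <- max(0L, brush - nrow(x)); pw <- max(0L, brush - ncol(x))
  if (ph == 0L && pw == 0L)
    return(as.matrix(EBImage::gblur(x, sigma = sigma)))
  top <- as.integer(ceiling(ph / 2)); lef <- as.integer(ceiling(pw / 2))
  ri <- c(rep(1L, top), seq_len(nrow(x)), rep(nrow(x), ph - top))
  ci <- c(rep(1L, lef), seq_len(ncol(x)), rep(ncol(x), pw - lef))
  big <- as.matrix(EBImage::gblur(x[ri, ci], sigma = sigma))
  big[top + seq_len(nrow(x)), lef + seq_len(ncol(x)), drop = FALSE]
}

#' Extract the NPC1-GFP localization pattern
#'
#' The first processing chain of the screen, applied to the GFP channel
#' in order: gamma transform (`x^gamma_gfp`), subtraction of a
#' Gaussian-blurred copy (`sigma = bg_sigma_px`) as background with
#' negatives clipped to zero, adaptive local-mean thresholding
#' (`at_window_px`, `at_offset`), morphological closing with a disc of
#' diameter `closing_disc_px`, connected-component labeling at the
#' configured connectivity, and removal of objects smaller than
#' `min_obj_area_px` pixels.
#'
#' @param img GFP-channel [image_field()].
#' @param cfg A [screen_config()].
#' @return A [label_mask()] result (`label_map`) of NPC1-GFP-positive
#'   objects.
#' @export
extract_gfp_pattern <- function(img, cfg = screen_config()) {
  x <- field_pixels(img, channel = "GFP", what = "extract_gfp_pattern")
  g <- x^cfg$gamma_gfp
  bg <- gaussian_blur(g, cfg$bg_sigma_px)
  sub <- pmax(g - bg, 0)
  bw <- adaptive_threshold(sub, cfg$at_window_px, cfg$at_offset)
  closed <- as.matrix(EBImage::closing(
    matrix(as.numeric(bw), nrow(bw), ncol(bw)),
    EBImage::makeBrush(as.integer(cfg$closing_disc_px), shape = "disc")))
  lm <- label_mask(closed > 0, cfg$connectivity)
  filter_objects(lm, min_area = cfg$min_obj_area_px)
}

#' Extract the overall cell area
#'
#' The second chain: a strong gamma compression (`x^gamma_cell`,
#' default exponent 0.1) to de-emphasize bright structures, Gaussian
#' blur (`sigma = cell_blur_sigma_px`), and global Otsu thresholding.
#' A constant (blank) image returns an all-background mask rather than
#' an error so blank wells flow through the pipeline.
#'
#' @param img GFP-channel [image_field()].
#' @param cfg A [screen_config()].
#' @return Logical matrix: the cell-area mask.
#' @export
extract_cell_area <- function(img, cfg = screen_config()) {
  x <- field_pixels(img, channel = "GFP", what = "extract_cell_area")
  g <- x^cfg$gamma_cell
  gb <- gaussian_blur(g, cfg$cell_blur_sigma_px)
  if (diff(range(gb)) < 1e-8)
    return(matrix(FALSE, nrow(x), ncol(x)))
  gb <- pmin(pmax(gb, 0), 1)  # gblur can overshoot marginally
  gb > EBImage::otsu(gb)
}

#' Segment nuclei from the Hoechst channel
#'
#' The third chain: disc mean filter (diameter `nuc_mean_disc_px`),
#' gamma transform (`x^gamma_nuc`), Otsu thresholding, Euclidean
#' distance transform of the foreground, and watershed segmentation of
#' the distance map (seeds are regional maxima separated by at least
#' `nuc_mean_disc_px` pixels) to split touching nuclei.  Objects are
#' kept only if `nuc_min_area_px < area < nuc_max_area_px` (strict).
#'
#' @param img HOECHST-channel [image_field()].
#' @param cfg A [screen_config()].
#' @return A `label_map` of nuclei.
#' @export
segment_nuclei <- function(img, cfg = screen_config()) {
  x <- field_pixels(img, channel = "HOECHST", what = "segment_nuclei")
  disc <- EBImage::makeBrush(as.integer(cfg$nuc_mean_disc_px),
                             shape = "disc")
  mf <- as.matrix(EBImage::filter2(x, disc / sum(disc),
                                   boundary = "replicate"))
  mf <- pmin(pmax(mf, 0), 1)
  g <- mf^cfg$gamma_nuc
  if (diff(range(g)) < 1e-8)
    return(relabel_consecutive(matrix(0L, nrow(x), ncol(x)),
                               cfg$connectivity))
  fg <- g > EBImage::otsu(g)
  if (!any(fg))
    return(relabel_consecutive(matrix(0L, nrow(x), ncol(x)),
                               cfg$connectivity))
  dm <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  ws <- EBImage::watershed(dm, tolerance = 1,
                           ext = as.integer(cfg$nuc_mean_disc_px))
  lm <- relabel_consecutive(matrix(as.integer(ws), nrow(ws), ncol(ws)),
                            cfg$connectivity)
  filter_objects(lm, min_area = cfg$nuc_min_area_px,
                 max_area = cfg$nuc_max_area_px, strict = TRUE)
}
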