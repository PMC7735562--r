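#' Screen processing configuration
#'
#' Collects every numeric parameter of the three image-processing chains
#' in one validated structure.  The defaults are the published settings of
#' the assay; any of them can be overridden, and a configuration can be
#' round-tripped through YAML with [read_screen_config()] /
#' [write_screen_config()].
#'
#' @param gamma_gfp Gamma exponent applied to the GFP image before
#'   background subtraction (intensities in `[0,1]`, transform `x^gamma`).
#' @param bg_sigma_px Gaussian sigma (pixels) of the blurred copy
#'   subtracted as background.
#' @param at_window_px Full width (pixels, odd) of the square local-mean
#'   window of the adaptive threshold.
#' @param at_offset Additive offset of the adaptive threshold.
#' @param closing_disc_px Diameter (pixels) of the disc structuring
#'   element used for morphological closing.
#' @param min_obj_area_px Objects smaller than this pixel count are
#'   removed from the GFP pattern.
#' @param gamma_cell Gamma exponent of the cell-area chain (small, to
#'   de-emphasize bright structures).
#' @param cell_blur_sigma_px Gaussian sigma (pixels) of the cell-area
#'   chain blur.
#' @param nuc_mean_disc_px Diameter (pixels) of the disc mean filter of
#'   the nuclei chain; also the minimum seed separation of the watershed.
#' @param gamma_nuc Gamma exponent of the nuclei chain.
#' @param nuc_min_area_px,nuc_max_area_px Retained nuclei must satisfy
#'   `nuc_min_area_px < area < nuc_max_area_px` (strict).
#' @param connectivity Pixel connectivity for object labeling, 4 or 8.
#' @return An object of class `screen_config` (a named list).
#' @examples
#' cfg <- screen_config()
#' cfg$at_offset
#' @export
screen_config <- function(gamma_gfp = 0.5,
                          bg_sigma_px = 35,
                          at_window_px = 25,
                          at_offset = 0.02,
                          closing_disc_px = 7,
                          min_obj_area_px = 50,
                          gamma_cell = 0.1,
                          cell_blur_sigma_px = 25,
                          nuc_mean_disc_px = 11,
                          gamma_nuc = 0.6,
                          nuc_min_area_px = 1000,
                          nuc_max_area_px = 7000,
                          connectivity = 8) {
  cfg <- list(gamma_gfp = gamma_gfp, bg_sigma_px = bg_sigma_px,
              at_window_px = at_window_px, at_offset = at_offset,
              closing_disc_px = closing_disc_px,
              min_obj_area_px = min_obj_area_px,
              gamma_cell = gamma_cell,
              cell_blur_sigma_px = cell_blur_sigma_px,
              nuc_mean_disc_px = nuc_mean_disc_px, gamma_nuc = gamma_nuc,
              nuc_min_area_px = nuc_min_area_px,
              nuc_max_area_px = nuc_max_area_px,
              connectivity = connectivity)
  validate_screen_config(cfg)
}

validate_screen_config <- function(cfg) {
  num <- c("gamma_gfp", "bg_sigma_px", "at_window_px", "closing_disc_px",
           "min_obj_area_px", "gamma_cell", "cell_blur_sigma_px",
           "nuc_mean_disc_px", "gamma_nuc", "nuc_min_area_px",
           "nuc_max_area_px")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("screen_config: '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (!is.numeric(cfg$at_offset) || cfg$at_offset < 0)
    stop("screen_config: 'at_offset' must be >= 0", call. = FALSE)
  if (cfg$at_window_px %% 2 == 0)
    stop("screen_config: 'at_window_px' must be odd", call. = FALSE)
  if (!cfg$connectivity %in% c(4, 8))
    stop("screen_config: 'connectivity' must be 4 or 8", call. = FALSE)
  if (cfg$nuc_min_area_px >= cfg$nuc_max_area_px)
    stop("screen_config: nuclear size filter bounds are inverted",
         call. = FALSE)
  structure(cfg, class = "screen_config")
}

#' Feature computation configuration
#'
#' @param small_obj_area_px Size threshold (pixel count) of the
#'   small-object area ratio: objects with `area < small_obj_area_px`
#'   count as "small".  The published assay does not print this value;
#'   500 px sits between typical vesicular puncta and reticular
#'   fragments and is reported in all outputs.
#' @param min_fields_for_valid_well Minimum number of qc-ok fields for a
#'   well to be considered valid.
#' @param min_mean_nuclei Wells whose mean nuclei count per field falls
#'   below this are flagged `low_cell_count` (cytotoxicity readout).
#' @param aggregate `"mean"` (default) or `"median"` across fields.
#' @param clamp_circularity Clamp per-object circularity at 1 to absorb
#'   digital-perimeter underestimation on tiny objects.
#' @param perimeter_method `"contour"` (sub-pixel smoothed contour
#'   length, default) or `"boundary"` (naive boundary pixel count).
#'   Circularity values are comparable only within one estimator.
#' @param contour_smooth Moving-average window (vertices) of the contour
#'   perimeter estimator.
#' @param gfp_int_pattern_only If `TRUE` (default) the GFP-intensity
#'   numerator sums raw intensity within the extracted pattern; if
#'   `FALSE`, over the whole image.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(small_obj_area_px = 500,
                           min_fields_for_valid_well = 3,
                           min_mean_nuclei = 5,
                           aggregate = c("mean", "median"),
                           clamp_circularity = TRUE,
                           perimeter_method = c("contour", "boundary"),
                           contour_smooth = 5,
                           gfp_int_pattern_only = TRUE) {
  aggregate <- match.arg(aggregate)
  perimeter_method <- match.arg(perimeter_method)
  if (!is.numeric(small_obj_area_px) || small_obj_area_px <= 0)
    stop("feature_config: 'small_obj_area_px' must be positive",
         call. = FALSE)
  structure(list(small_obj_area_px = small_obj_area_px,
                 min_fields_for_valid_well = min_fields_for_valid_well,
                 min_mean_nuclei = min_mean_nuclei,
                 aggregate = aggregate,
                 clamp_circularity = clamp_circularity,
                 perimeter_method = perimeter_method,
                 contour_smooth = contour_smooth,
                 gfp_int_pattern_only = gfp_int_pattern_only),
            class = "feature_config")
}

#' Read / write a screen configuration as YAML
#'
#' Unknown keys in the YAML file are rejected; missing keys fall back to
#' the published defaults.
#'
#' @param path Path of the YAML file.
#' @return [read_screen_config()] returns a `screen_config`;
#'   [write_screen_config()] invisibly returns `path`.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown screen_config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(screen_config, vals)
}

#' @rdname read_screen_config
#' @param cfg A `screen_config` object.
#' @export
write_screen_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "screen_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
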