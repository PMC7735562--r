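#' Mean per-object circularity
#'
#' Circularity of one object is the ratio of its area to the area of a
#' circle with the same perimeter, `4 * pi * area / perimeter^2`: 1 for
#' a circle, lower for elongated or branched shapes.  The score of a
#' field is the mean over all detected NPC1-GFP objects.  Per-object
#' values are clamped at 1 by default, absorbing digital-perimeter
#' underestimation on tiny objects.  An empty label map yields `NaN`
#' (a flagged, undefined feature), not an error.
#'
#' @param objects A `label_map`.
#' @param fcfg A [feature_config()] (perimeter estimator and clamping).
#' @return Mean circularity, or `NaN` if there are no objects.
#' @export
circularity <- function(objects, fcfg = feature_config()) {
  if (n_objects(objects) == 0) return(NaN)
  a <- object_areas(objects)
  p <- object_perimeters(objects, method = fcfg$perimeter_method,
                         smooth_window = fcfg$contour_smooth)
  v <- 4 * pi * a / p^2
  if (fcfg$clamp_circularity) v <- pmin(v, 1)
  mean(v)
}

#' Small-object area ratio
#'
#' Fraction of the total NPC1-GFP-positive area contributed by objects
#' with `area < small_obj_area_px` (strict at the threshold).  High for
#' vesicular, punctate localization; low for large reticular networks.
#'
#' @param objects A `label_map`.
#' @param fcfg A [feature_config()].
#' @return Ratio in `[0, 1]`, or `NaN` if there are no objects.
#' @export
small_obj_ratio <- function(objects, fcfg = feature_config()) {
  a <- object_areas(objects)
  if (!length(a)) return(NaN)
  sum(a[a < fcfg$small_obj_area_px]) / sum(a)
}

#' GFP intensity per cell area
#'
#' Sum of raw (pre-gamma) GFP intensities over the pixels of the
#' extracted pattern, divided by the pixel count of the cell-area mask.
#' A proxy for mutant-protein expression level.  An empty cell mask
#' yields `NaN` (flagged); an empty pattern over a non-empty mask
#' yields 0.
#'
#' @param img GFP-channel [image_field()] (raw intensities).
#' @param pattern `label_map` from [extract_gfp_pattern()].
#' @param cells Logical cell-area mask from [extract_cell_area()].
#' @param pattern_only If `FALSE`, sum intensity over the whole image
#'   instead of the extracted pattern.
#' @return GFP intensity per cell-area pixel, or `NaN`.
#' @export
gfp_int <- function(img, pattern, cells, pattern_only = TRUE) {
  x <- field_pixels(img, what = "gfp_int")
  if (!identical(dim(x), dim(pattern$labels)) ||
      !identical(dim(x), dim(cells)))
    stop("gfp_int: image, pattern and cell mask shapes differ",
         call. = FALSE)
  ncell <- sum(cells)
  if (ncell == 0) return(NaN)
  num <- if (pattern_only) sum(x[pattern$labels > 0]) else sum(x)
  num / ncell
}

#' Compute all per-field features
#'
#' Runs the three segmentation chains on a GFP/Hoechst image pair and
#' computes the field-level morphological scores.  A field with zero
#' GFP objects gets `NaN` shape features and `qc = "no_objects"`.
#'
#' @param gfp,hoechst The two [image_field()]s of one field (equal
#'   size).
#' @param scfg A [screen_config()].
#' @param fcfg A [feature_config()].
#' @return A one-row `data.frame` with columns `circularity`,
#'   `small_obj_ratio`, `gfp_int`, `npc1_area_px`, `cell_area_px`,
#'   `n_nuclei`, `mean_nuc_area_px`, `n_objects`, `qc`.
#' @export
compute_field_features <- function(gfp, hoechst,
                                   scfg = screen_config(),
                                   fcfg = feature_config()) {
  gx <- field_pixels(gfp, channel = "GFP", what = "compute_field_features")
  hx <- field_pixels(hoechst, channel = "HOECHST",
                     what = "compute_field_features")
  if (!identical(dim(gx), dim(hx)))
    stop("compute_field_features: GFP and Hoechst shapes differ",
         call. = FALSE)
  pattern <- extract_gfp_pattern(gfp, scfg)
  cells <- extract_cell_area(gfp, scfg)
  nuclei <- segment_nuclei(hoechst, scfg)
  nobj <- n_objects(pattern)
  nnuc <- n_objects(nuclei)
  data.frame(
    circularity = circularity(pattern, fcfg),
    small_obj_ratio = small_obj_ratio(pattern, fcfg),
    gfp_int = gfp_int(gx, pattern, cells,
                      pattern_only = fcfg$gfp_int_pattern_only),
    npc1_area_px = sum(object_areas(pattern)),
    cell_area_px = sum(cells),
    n_nuclei = nnuc,
    mean_nuc_area_px = if (nnuc) mean(object_areas(nuclei)) else NaN,
    n_objects = nobj,
    qc = if (nobj == 0) "no_objects" else "ok",
    stringsAsFactors = FALSE)
}

#' Aggregate field features into a well record
#'
#' Shape features are averaged (mean by default, median via
#' `fcfg$aggregate`) over fields with `qc == "ok"`; cell/nuclei counts
#' are averaged over all fields.  Wells with fewer than
#' `min_fields_for_valid_well` valid fields are flagged and excluded
#' downstream.
#'
#' @param fields Data frame of per-field rows from
#'   [compute_field_features()].
#' @param meta Named list or one-row data frame with `plate`, `well`,
#'   `treatment`, `dose_uM`, `role`.
#' @param fcfg A [feature_config()].
#' @return One-row `data.frame` (a well record).
#' @export
aggregate_well <- function(fields, meta, fcfg = feature_config()) {
  if (!is.data.frame(fields) || nrow(fields) == 0)
    stop("aggregate_well: at least one field is required", call. = FALSE)
  agg <- if (fcfg$aggregate == "median") stats::median else mean
  ok <- fields$qc == "ok"
  shape_cols <- c("circularity", "small_obj_ratio", "gfp_int",
                  "npc1_area_px", "n_objects")
  count_cols <- c("cell_area_px", "n_nuclei", "mean_nuc_area_px")
  rec <- data.frame(plate = meta$plate, well = meta$well,
                    treatment = meta$treatment, dose_uM = meta$dose_uM,
                    role = meta$role, stringsAsFactors = FALSE)
  for (col in shape_cols)
    rec[[col]] <- if (any(ok)) agg(fields[[col]][ok]) else NaN
  for (col in count_cols)
    rec[[col]] <- agg(fields[[col]][!is.na(fields[[col]])])
  rec$n_valid_fields <- sum(ok)
  rec$qc_flag <- if (sum(ok) < fcfg$min_fields_for_valid_well)
    "no_objects"
  else if (is.finite(rec$n_nuclei) && rec$n_nuclei < fcfg$min_mean_nuclei)
    "low_cell_count"
  else "ok"
  rec[, WELL_RECORD_COLUMNS]
}
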