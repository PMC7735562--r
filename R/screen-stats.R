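SCREEN_FEATURES <- c("circularity", "small_obj_ratio", "gfp_int")

#' Robust Z score of one plate's values
#'
#' `(x - median) / (mad_constant * raw MAD)`: the plate-wise
#' nonparametric analogue of standardization.  `NaN`/`NA` inputs
#' propagate as `NA` without affecting the median or MAD.
#'
#' @param values Numeric vector (one plate's values of one feature).
#' @param mad_constant Consistency constant; 1.4826 makes the scaled
#'   MAD estimate an sd under normality.  Recorded in all outputs.
#' @param plate_id Optional id used in the degenerate-plate error.
#' @return Numeric vector of robust Z scores.
#' @export
robust_z <- function(values, mad_constant = 1.4826, plate_id = NULL) {
  v <- values[is.finite(values)]
  if (length(v) < 4)
    stop("robust_z: need at least 4 finite values",
         if (!is.null(plate_id)) paste0(" (plate ", plate_id, ")"),
         call. = FALSE)
  med <- stats::median(v)
  rawmad <- stats::median(abs(v - med))
  if (rawmad == 0)
    stop("robust_z: degenerate plate (MAD = 0)",
         if (!is.null(plate_id)) paste0(" for plate ", plate_id),
         call. = FALSE)
  (values - med) / (mad_constant * rawmad)
}

#' Plate-wise robust-Z normalization of a feature table
#'
#' For every plate, the median and MAD of each screen feature are
#' computed over the qc-ok wells of the null-centring roles
#' (`center_roles`, default library + vehicle + blank; positive-control
#' dose series are excluded so they cannot bias the null centre) and
#' every well of the plate is transformed to a robust Z score
#' (`robust_z_<feature>` columns).
#'
#' @param records Well-record data frame ([compute_plate_features()]).
#' @param mad_constant See [robust_z()].
#' @param center_roles Roles over which plate median/MAD are computed.
#' @return The input data frame with `robust_z_*` columns appended;
#'   attribute `mad_constant` records the convention.
#' @export
normalize_features <- function(records, mad_constant = 1.4826,
                               center_roles = c("library", "vehicle",
                                                "blank")) {
  stopifnot(is.data.frame(records))
  out <- records
  for (f in SCREEN_FEATURES) out[[paste0("robust_z_", f)]] <- NA_real_
  for (p in unique(records$plate)) {
    on_plate <- records$plate == p
    centre <- on_plate & records$role %in% center_roles &
      records$qc_flag == "ok"
    for (f in SCREEN_FEATURES) {
      v <- records[[f]][centre]
      v <- v[is.finite(v)]
      if (length(v) < 4)
        stop("normalize_features: fewer than 4 usable centring wells ",
             "on plate ", p, call. = FALSE)
      med <- stats::median(v)
      rawmad <- stats::median(abs(v - med))
      if (rawmad == 0)
        stop("normalize_features: degenerate plate (MAD = 0) for ",
             "feature '", f, "' on plate ", p, call. = FALSE)
      out[[paste0("robust_z_", f)]][on_plate] <-
        (records[[f]][on_plate] - med) / (mad_constant * rawmad)
    }
  }
  attr(out, "mad_constant") <- mad_constant
  out
}

#' Z'-factor of a screening window
#'
#' `1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample sds —
#' the classical assay-quality statistic: above 0.5 indicates an
#' excellent assay window.  Equal group means return `-Inf` (flagged in
#' the QC report) rather than an error.  A robust variant using
#' median/MAD is available for diagnostics but is never the headline
#' QC number.
#'
#' @param pos,neg Numeric vectors (at least 2 values each).
#' @return Z' factor (at most 1).
#' @export
z_prime <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2)
    stop("z_prime: need at least 2 values per group", call. = FALSE)
  denom <- abs(mean(pos) - mean(neg))
  if (denom == 0) return(-Inf)
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / denom
}

#' @rdname z_prime
#' @export
z_prime_robust <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2)
    stop("z_prime_robust: need at least 2 values per group", call. = FALSE)
  denom <- abs(stats::median(pos) - stats::median(neg))
  if (denom == 0) return(-Inf)
  1 - 3 * (stats::mad(pos) + stats::mad(neg)) / denom
}

#' Per-plate assay QC report
#'
#' Z' factor per plate and feature between positive-control wells at
#' the highest dose present and vehicle wells, plus well counts and
#' flags.
#'
#' @param normalized Output of [normalize_features()].
#' @return Data frame: one row per plate and feature with `z_prime`,
#'   `n_pos`, `n_neg`, `n_wells`, `n_flagged`, `degenerate`.
#' @export
qc_report <- function(normalized) {
  out <- NULL
  for (p in unique(normalized$plate)) {
    pl <- normalized[normalized$plate == p & normalized$qc_flag == "ok", ]
    posw <- pl[pl$role == "positive_control", ]
    if (nrow(posw)) posw <- posw[posw$dose_uM == max(posw$dose_uM), ]
    negw <- pl[pl$role == "vehicle", ]
    for (f in SCREEN_FEATURES) {
      zp <- if (nrow(posw) >= 2 && nrow(negw) >= 2)
        z_prime(posw[[f]], negw[[f]]) else NA_real_
      out <- rbind(out, data.frame(
        plate = p, feature = f, z_prime = zp,
        n_pos = nrow(posw), n_neg = nrow(negw),
        n_wells = sum(normalized$plate == p),
        n_flagged = sum(normalized$plate == p &
                        normalized$qc_flag != "ok"),
        degenerate = is.infinite(zp) && zp < 0,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Calibrate hit thresholds from marginally active positive controls
#'
#' Per-feature medians of the robust Z scores of the
#' `marginal_positive` wells — the screen's operating point: a library
#' well is a hit only if it beats the marginally active chaperone on
#' every feature.  Wells with any non-finite feature are excluded; at
#' least 2 usable wells are required.
#'
#' @param normalized Output of [normalize_features()].
#' @param role Role of the calibration wells.
#' @return Named list of class `hit_thresholds` with `circularity_t`,
#'   `small_obj_ratio_t`, `gfp_int_t` and `n_wells`.
#' @export
calibrate_thresholds <- function(normalized, role = "marginal_positive") {
  zc <- paste0("robust_z_", SCREEN_FEATURES)
  m <- normalized[normalized$role == role & normalized$qc_flag == "ok", ]
  usable <- rowSums(!is.finite(as.matrix(m[, zc]))) == 0
  m <- m[usable, ]
  if (nrow(m) < 2)
    stop("calibrate_thresholds: need at least 2 usable wells with ",
         "role '", role, "', got ", nrow(m), call. = FALSE)
  structure(list(circularity_t = stats::median(m$robust_z_circularity),
                 small_obj_ratio_t = stats::median(m$robust_z_small_obj_ratio),
                 gfp_int_t = stats::median(m$robust_z_gfp_int),
                 n_wells = nrow(m)),
            class = "hit_thresholds")
}

#' Multiparameter hit calling
#'
#' A well exceeds the thresholds iff its robust Z score is strictly
#' greater than the calibrated threshold for all three features
#' (`exceeds_all`).  Only library-role wells are eligible to be hits
#' (`is_hit = exceeds_all & role == "library"`); control wells are
#' reported with their exceedance but never called.  QC-flagged wells
#' are reported as excluded.
#'
#' @param normalized Output of [normalize_features()].
#' @param thresholds A `hit_thresholds` object.
#' @return Data frame with `plate`, `well`, `role`, robust-Z columns,
#'   `excluded`, `exceeds_all`, `is_hit`.
#' @export
call_hits <- function(normalized, thresholds) {
  stopifnot(inherits(thresholds, "hit_thresholds"))
  zc <- paste0("robust_z_", SCREEN_FEATURES)
  t3 <- c(thresholds$circularity_t, thresholds$small_obj_ratio_t,
          thresholds$gfp_int_t)
  z <- as.matrix(normalized[, zc])
  excluded <- normalized$qc_flag != "ok" | rowSums(!is.finite(z)) > 0
  exceeds <- !excluded &
    z[, 1] > t3[1] & z[, 2] > t3[2] & z[, 3] > t3[3]
  data.frame(plate = normalized$plate, well = normalized$well,
             treatment = normalized$treatment,
             dose_uM = normalized$dose_uM, role = normalized$role,
             robust_z_circularity = z[, 1],
             robust_z_small_obj_ratio = z[, 2],
             robust_z_gfp_int = z[, 3],
             excluded = excluded,
             exceeds_all = exceeds,
             is_hit = exceeds & normalized$role == "library",
             stringsAsFactors = FALSE)
}

#' Dose-response summary of one treatment
#'
#' Per-dose mean, sample SD and n of the robust Z scores of each
#' feature; doses with no wells are omitted, single wells report
#' `NA` SD with `n = 1`.
#'
#' @param normalized Output of [normalize_features()].
#' @param treatment Treatment name.
#' @return Data frame: one row per dose and feature.
#' @export
dose_response_summary <- function(normalized, treatment) {
  m <- normalized[normalized$treatment == treatment &
                  normalized$qc_flag == "ok", ]
  if (nrow(m) == 0)
    stop("dose_response_summary: no wells with treatment '", treatment,
         "'", call. = FALSE)
  out <- NULL
  for (d in sort(unique(m$dose_uM))) {
    sub <- m[m$dose_uM == d, ]
    for (f in SCREEN_FEATURES) {
      v <- sub[[paste0("robust_z_", f)]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      out <- rbind(out, data.frame(
        treatment = treatment, dose_uM = d, feature = f,
        mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE))
    }
  }
  out
}
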