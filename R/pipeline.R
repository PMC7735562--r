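#' Compute well features for a whole plate layout from disk
#'
#' Reads every GFP/Hoechst field pair of the layout, runs the three
#' segmentation chains and the feature scores per field
#' ([compute_field_features()]), and aggregates fields into well
#' records ([aggregate_well()]).
#'
#' @param layout A [plate_layout()].
#' @param dir Directory the layout's `path` column is relative to.
#' @param scfg A [screen_config()].
#' @param fcfg A [feature_config()].
#' @return Data frame of well records, one row per (plate, well).
#' @export
compute_plate_features <- function(layout, dir = ".",
                                   scfg = screen_config(),
                                   fcfg = feature_config()) {
  stopifnot(inherits(layout, "plate_layout"))
  gf <- layout[layout$channel == "GFP", ]
  wells <- unique(gf[, c("plate", "well", "treatment", "dose_uM", "role")])
  recs <- NULL
  for (k in seq_len(nrow(wells))) {
    wrow <- wells[k, ]
    sel <- gf[gf$plate == wrow$plate & gf$well == wrow$well, ]
    fields <- NULL
    for (j in seq_len(nrow(sel))) {
      frow <- sel[j, ]
      hrow <- layout[layout$plate == frow$plate &
                     layout$well == frow$well &
                     layout$field == frow$field &
                     layout$channel == "HOECHST", ]
      gfp <- read_field_image(file.path(dir, frow$path), "GFP")
      hoe <- read_field_image(file.path(dir, hrow$path[1]), "HOECHST")
      fields <- rbind(fields,
                      compute_field_features(gfp, hoe, scfg, fcfg))
    }
    recs <- rbind(recs, aggregate_well(fields, wrow, fcfg))
  }
  rownames(recs) <- NULL
  recs
}

#' Simulate a screen and compute its well features in memory
#'
#' Renders every field of the layout with [render_field()] (same
#' dose-response, toxicity and seeding rules as [generate_plate()])
#' and pipes it straight into the segmentation and feature chain
#' without touching disk — the fast path for large simulated screens.
#'
#' @param layout A [plate_layout()] (or data frame with the layout
#'   columns; `path` entries are not used).
#' @param models Named list of [dose_response_model()]s per treatment.
#' @param base A [phenotype_params()].
#' @param seed Master seed (per-field seeds via [field_seed()]).
#' @param scfg,fcfg Processing and feature configuration.
#' @param field_px Field edge length in pixels.
#' @return Data frame of well records with a `theta_true` column.
#' @export
simulate_screen <- function(layout, models, base = phenotype_params(),
                            seed = 1, scfg = screen_config(),
                            fcfg = feature_config(), field_px = 512) {
  if (!inherits(layout, "plate_layout")) layout <- plate_layout(layout)
  gf <- layout[layout$channel == "GFP", ]
  missing_models <- setdiff(unique(gf$treatment), names(models))
  if (length(missing_models))
    stop("simulate_screen: no model for treatment(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  wells <- unique(gf[, c("plate", "well", "treatment", "dose_uM", "role")])
  recs <- NULL
  for (k in seq_len(nrow(wells))) {
    wrow <- wells[k, ]
    model <- models[[wrow$treatment]]
    th <- theta_from_dose(wrow$dose_uM, model)
    expr <- 1 + model$expr_gain * hill_fraction(wrow$dose_uM, model)
    surv <- if (is.finite(model$tox_dose_uM))
      model$tox_dose_uM / (wrow$dose_uM + model$tox_dose_uM) else 1
    sel <- gf[gf$plate == wrow$plate & gf$well == wrow$well, ]
    fields <- NULL
    for (j in seq_len(nrow(sel))) {
      fs <- field_seed(seed, wrow$plate, wrow$well, sel$field[j])
      set.seed(fs)
      ncell <- if (surv < 1) rbinom(1, base$n_cells, surv)
               else base$n_cells
      p <- base
      p$theta <- th; p$expression_scale <- expr; p$n_cells <- ncell
      fld <- render_field(p, height = field_px, width = field_px,
                          seed = fs + 1L)
      fields <- rbind(fields, compute_field_features(
        fld$gfp, fld$hoechst, scfg, fcfg))
    }
    rec <- aggregate_well(fields, wrow, fcfg)
    rec$theta_true <- th
    recs <- rbind(recs, rec)
  }
  rownames(recs) <- NULL
  recs
}

#' Build a simple screen layout in memory
#'
#' Convenience constructor for simulated plates: given per-plate well
#' specifications, expands to one row per field and channel with
#' deterministic file names.
#'
#' @param wells Data frame with columns `plate`, `well`, `treatment`,
#'   `dose_uM`, `role` (one row per well).
#' @param n_fields Fields per well.
#' @return A [plate_layout()].
#' @export
expand_layout <- function(wells, n_fields = 6) {
  rows <- NULL
  for (k in seq_len(nrow(wells))) {
    w <- wells[k, ]
    for (f in seq_len(n_fields)) for (ch in c("GFP", "HOECHST")) {
      rows <- rbind(rows, data.frame(
        plate = w$plate, well = w$well, field = f, channel = ch,
        path = sprintf("%s_%s_f%d_%s.tif", w$plate, w$well, f,
                       tolower(ch)),
        treatment = w$treatment, dose_uM = w$dose_uM, role = w$role,
        stringsAsFactors = FALSE))
    }
  }
  plate_layout(rows, max_fields = n_fields)
}
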