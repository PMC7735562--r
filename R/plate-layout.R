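WELL_ROLES <- c("library", "vehicle", "positive_control",
                "marginal_positive", "blank")

LAYOUT_COLUMNS <- c("plate", "well", "field", "channel", "path",
                    "treatment", "dose_uM", "role")

#' Read and validate a plate layout
#'
#' The layout CSV maps every image file to its plate, well, field,
#' channel, treatment, dose and role.  Validation enforces the on-disk
#' contract of the pipeline: the `(plate, well, field, channel)` key is
#' unique, every GFP field has a matching Hoechst field, a well has at
#' most `max_fields` fields, and treatment/dose/role are constant within
#' a well.
#'
#' @param path CSV file with header columns
#'   `plate,well,field,channel,path,treatment,dose_uM,role`.
#' @param max_fields Maximum number of fields per well (acquisition
#'   design default: 6).
#' @param require_hoechst Require a HOECHST partner for every GFP field
#'   (the screen's two-channel contract); set `FALSE` for single-channel
#'   layouts such as filipin plates.
#' @return A `data.frame` of class `plate_layout`.
#' @export
read_plate_layout <- function(path, max_fields = 6, require_hoechst = TRUE) {
  if (!file.exists(path))
    stop("layout file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  plate_layout(df, max_fields = max_fields,
               require_hoechst = require_hoechst)
}

#' @rdname read_plate_layout
#' @param df A data frame with the layout columns.
#' @export
plate_layout <- function(df, max_fields = 6, require_hoechst = TRUE) {
  missing_cols <- setdiff(LAYOUT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("layout is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$field <- as.integer(df$field)
  df$dose_uM <- as.numeric(df$dose_uM)
  if (any(is.na(df$field)) || any(df$field < 1))
    stop("layout: 'field' must be an integer >= 1", call. = FALSE)
  if (any(is.na(df$dose_uM)) || any(df$dose_uM < 0))
    stop("layout: 'dose_uM' must be a non-negative number", call. = FALSE)
  badch <- setdiff(unique(df$channel), FIELD_CHANNELS)
  if (length(badch))
    stop("layout: unknown channel(s) ", paste(badch, collapse = ", "),
         "; allowed: ", paste(FIELD_CHANNELS, collapse = ", "),
         call. = FALSE)
  badrole <- setdiff(unique(df$role), WELL_ROLES)
  if (length(badrole))
    stop("layout: unknown role(s) ", paste(badrole, collapse = ", "),
         "; allowed: ", paste(WELL_ROLES, collapse = ", "), call. = FALSE)
  key <- paste(df$plate, df$well, df$field, df$channel, sep = "\r")
  if (anyDuplicated(key))
    stop("layout: duplicate (plate, well, field, channel) entries: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])),
               collapse = "; "), call. = FALSE)
  if (require_hoechst) {
    fkey <- function(ch) {
      s <- df[df$channel == ch, ]
      paste(s$plate, s$well, s$field, sep = "\r")
    }
    orphans <- setdiff(fkey("GFP"), fkey("HOECHST"))
    if (length(orphans))
      stop("layout: GFP fields without a matching HOECHST field: ",
           paste(gsub("\r", "/", orphans), collapse = "; "), call. = FALSE)
  }
  wellkey <- paste(df$plate, df$well, sep = "\r")
  nf <- tapply(df$field, wellkey, function(x) length(unique(x)))
  if (any(nf > max_fields))
    stop("layout: well(s) with more than ", max_fields, " fields: ",
         paste(gsub("\r", "/", names(nf)[nf > max_fields]), collapse = "; "),
         call. = FALSE)
  for (col in c("treatment", "dose_uM", "role")) {
    nu <- tapply(df[[col]], wellkey, function(x) length(unique(x)))
    if (any(nu > 1))
      stop("layout: '", col, "' varies within well(s) ",
           paste(gsub("\r", "/", names(nu)[nu > 1]), collapse = "; "),
           call. = FALSE)
  }
  class(df) <- c("plate_layout", "data.frame")
  df
}

FEATURE_COLUMNS <- c("circularity", "small_obj_ratio", "gfp_int",
                     "npc1_area_px", "cell_area_px", "n_nuclei",
                     "mean_nuc_area_px", "n_objects")

WELL_RECORD_COLUMNS <- c("plate", "well", "treatment", "dose_uM", "role",
                         FEATURE_COLUMNS, "n_valid_fields", "qc_flag")

#' Write / read a per-well feature table
#'
#' One row per well, deterministic column order, NaN/NA features
#' serialized as empty cells (such wells carry a non-`ok` `qc_flag`).
#' The round trip `read_feature_table(write_feature_table(x))` is the
#' identity on valid records (floats to 12 significant digits).
#'
#' @param records Data frame of well records (as produced by
#'   [aggregate_well()] / [compute_plate_features()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("write_feature_table: 'records' must be a non-empty data frame",
         call. = FALSE)
  missing_cols <- setdiff(WELL_RECORD_COLUMNS, names(records))
  if (length(missing_cols))
    stop("write_feature_table: records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- records[, WELL_RECORD_COLUMNS]
  for (col in FEATURE_COLUMNS)
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 12, format = "g"))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_feature_table: cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop("feature table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(plate = "character",
                                       well = "character"))
  for (col in FEATURE_COLUMNS) df[[col]] <- as.numeric(df[[col]])
  df
}
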