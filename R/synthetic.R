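#' Phenotype parameters of the synthetic-field generator
#'
#' The generator emulates the two localization phenotypes the screen
#' discriminates: a reticular, ER-like network (branched filaments, low
#' circularity) versus vesicular LE/L-like puncta (small, round).  The
#' fraction `theta` of each cell's GFP signal placed in puncta is the
#' phenotype axis: 0 = pure reticular, 1 = pure punctate.
#'
#' Beyond the phenotype fields, the generator models two features of
#' widefield epifluorescence acquisition that the processing chains
#' rely on: a uniform background floor (`background_floor`, camera
#' offset plus medium autofluorescence) and cell-proportional
#' out-of-focus haze (`haze_amp`, Gaussian-blurred cell occupancy).
#' Both raise the local intensity baseline, which the gamma transform
#' of the GFP chain then compresses; without them, uniform sensor noise
#' on a zero baseline is amplified far beyond its nominal sd.
#'
#' @param theta Fraction of GFP signal in puncta, in `[0,1]`.
#' @param expression_scale Multiplier on the total GFP signal per cell.
#' @param n_cells Cells per field.
#' @param puncta_per_cell Number of vesicular puncta per cell.
#' @param puncta_radius_px Gaussian radius (sd, pixels) of one punctum.
#' @param noise_sd Sd of the additive i.i.d. Gaussian sensor noise.
#' @param unit_signal Total GFP intensity-sum per cell at
#'   `expression_scale = 1` (arbitrary units on the `[0,1]` scale).
#' @param haze_amp Amplitude of the out-of-focus haze.
#' @param background_floor Uniform background intensity.
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(theta = 0.15,
                             expression_scale = 1,
                             n_cells = 30,
                             puncta_per_cell = 8,
                             puncta_radius_px = 4,
                             noise_sd = 0.02,
                             unit_signal = 600,
                             haze_amp = 0.40,
                             background_floor = 0.12) {
  if (!is.numeric(theta) || theta < 0 || theta > 1)
    stop("phenotype_params: 'theta' must lie in [0,1]", call. = FALSE)
  if (expression_scale <= 0)
    stop("phenotype_params: 'expression_scale' must be positive",
         call. = FALSE)
  if (n_cells < 0 || n_cells != round(n_cells))
    stop("phenotype_params: 'n_cells' must be a non-negative integer",
         call. = FALSE)
  if (puncta_per_cell < 1)
    stop("phenotype_params: 'puncta_per_cell' must be >= 1", call. = FALSE)
  if (puncta_radius_px <= 0 || noise_sd < 0)
    stop("phenotype_params: invalid puncta radius or noise sd",
         call. = FALSE)
  structure(list(theta = theta, expression_scale = expression_scale,
                 n_cells = as.integer(n_cells),
                 puncta_per_cell = as.integer(puncta_per_cell),
                 puncta_radius_px = puncta_radius_px,
                 noise_sd = noise_sd, unit_signal = unit_signal,
                 haze_amp = haze_amp,
                 background_floor = background_floor),
            class = "phenotype_params")
}

#' Hill dose-response model of the phenotype shift
#'
#' Maps a treatment dose to the punctate fraction `theta` by a Hill
#' curve, with an optional cytotoxicity term: the expected cell count
#' is multiplied by `tox_dose_uM / (dose + tox_dose_uM)`, so it halves
#' at `dose = tox_dose_uM`.  The expression response (GFP increase with
#' chaperone dose) follows the same Hill fraction scaled by
#' `expr_gain`.
#'
#' @param theta_min,theta_max Phenotype bounds (`theta_min <=
#'   theta_max`).
#' @param ec50_uM Dose of half-maximal phenotype shift (micromolar).
#' @param hill Hill coefficient.
#' @param tox_dose_uM Dose at which the expected cell count halves
#'   (`Inf` = no toxicity).
#' @param expr_gain Fractional increase of `expression_scale` at
#'   saturating dose.
#' @return An object of class `dose_response_model`.
#' @export
dose_response_model <- function(theta_min = 0.15, theta_max = 0.85,
                                ec50_uM = 1, hill = 1,
                                tox_dose_uM = Inf, expr_gain = 2.5) {
  if (theta_min > theta_max)
    stop("dose_response_model: theta_min must be <= theta_max",
         call. = FALSE)
  if (any(c(theta_min, theta_max) < 0) || any(c(theta_min, theta_max) > 1))
    stop("dose_response_model: theta bounds must lie in [0,1]",
         call. = FALSE)
  if (ec50_uM <= 0 || hill <= 0 || tox_dose_uM <= 0)
    stop("dose_response_model: ec50, hill and tox dose must be positive",
         call. = FALSE)
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 ec50_uM = ec50_uM, hill = hill,
                 tox_dose_uM = tox_dose_uM, expr_gain = expr_gain),
            class = "dose_response_model")
}

#' Zero-effect model (vehicle / blank wells)
#' @param base A `dose_response_model` providing `theta_min`.
#' @return A `dose_response_model` pinned at `theta_min`.
#' @export
null_model <- function(base = dose_response_model()) {
  dose_response_model(theta_min = base$theta_min,
                      theta_max = base$theta_min,
                      ec50_uM = base$ec50_uM, hill = base$hill,
                      tox_dose_uM = Inf, expr_gain = 0)
}

#' Hill fraction and theta at a dose
#'
#' `hill_fraction()` returns `dose^h / (dose^h + ec50^h)` (0 at dose 0);
#' `theta_from_dose()` maps it onto `[theta_min, theta_max]`.
#'
#' @param dose_uM Non-negative dose (micromolar).
#' @param model A [dose_response_model()].
#' @return Numeric scalar (vectorized over `dose_uM`).
#' @export
theta_from_dose <- function(dose_uM, model) {
  stopifnot(inherits(model, "dose_response_model"))
  model$theta_min +
    (model$theta_max - model$theta_min) * hill_fraction(dose_uM, model)
}

#' @rdname theta_from_dose
#' @export
hill_fraction <- function(dose_uM, model) {
  if (any(dose_uM < 0)) stop("dose must be non-negative", call. = FALSE)
  dh <- dose_uM^model$hill
  ifelse(dose_uM == 0, 0, dh / (dh + model$ec50_uM^model$hill))
}

# additive Gaussian stamp, truncated at 3 sd, clipped at image borders
stamp_gaussian <- function(img, r0, c0, sd, total) {
  R <- ceiling(3 * sd)
  rlo <- max(1, round(r0) - R); rhi <- min(nrow(img), round(r0) + R)
  clo <- max(1, round(c0) - R); chi <- min(ncol(img), round(c0) + R)
  if (rhi < rlo || chi < clo) return(img)
  rr <- rlo:rhi; cc <- clo:chi
  k <- outer(rr - r0, cc - c0,
             function(a, b) exp(-(a^2 + b^2) / (2 * sd^2)))
  img[rr, cc] <- img[rr, cc] + k / (2 * pi * sd^2) * total
  img
}

#' Render one synthetic two-channel field
#'
#' For each cell the generator places a nucleus (filled ellipse with
#' area drawn uniformly in 2000-5000 px, additive intensity) in the
#' Hoechst channel.  In the GFP channel the cell's total signal
#' (`expression_scale * unit_signal`) is split: a fraction `1 - theta`
#' goes into a reticular component (six connected persistent
#' random-walk filaments dilated to 3 px width anchored around the
#' nucleus, plus six short detached peripheral fragments), and `theta`
#' into `puncta_per_cell` Gaussian puncta scattered in a perinuclear
#' annulus.  Cell-proportional haze and the background floor are added,
#' then i.i.d. Gaussian noise (`noise_sd`), and the result is clipped
#' to `[0,1]` (detector saturation).  Ground-truth totals are recorded
#' before clipping.  The same seed reproduces the field bit for bit.
#'
#' @param params A [phenotype_params()].
#' @param height,width Field size in pixels (>= 256 for the default
#'   cell geometry).
#' @param seed Integer seed.
#' @return List with `gfp` and `hoechst` ([image_field()]s) and
#'   `truth`: a list with `n_nuclei`, `nucleus_centroids` (n x 2
#'   matrix), `total_gfp_in_puncta`, `total_gfp_in_reticulum`,
#'   `cell_mask_area_px`.
#' @export
render_field <- function(params = phenotype_params(), height = 512,
                         width = 512, seed = 1) {
  stopifnot(inherits(params, "phenotype_params"))
  if (height < 256 || width < 256)
    stop("render_field: field must be at least 256 x 256 for the ",
         "default cell geometry", call. = FALSE)
  if (params$n_cells > (height * width) / 8000)
    stop("render_field: geometry too small for ", params$n_cells,
         " cells", call. = FALSE)
  set.seed(as.integer(seed))
  H <- height; W <- width
  gfp <- matrix(0, H, W); hoe <- matrix(0, H, W)
  occupancy <- matrix(0, H, W)
  nc <- params$n_cells
  centroids <- matrix(numeric(0), 0, 2)
  tot_punct <- 0; tot_ret <- 0
  # soft minimum-distance cell placement (confluent monolayer)
  ctr <- matrix(NA_real_, nc, 2)
  placed <- 0
  while (placed < nc) {
    cand <- c(runif(1, 40, H - 40), runif(1, 40, W - 40))
    ok <- placed == 0 ||
      min(sqrt(rowSums((ctr[seq_len(placed), , drop = FALSE] -
                        matrix(cand, placed, 2, byrow = TRUE))^2))) > 55
    if (ok || runif(1) < 0.15) {
      placed <- placed + 1
      ctr[placed, ] <- cand
    }
  }
  S_unit <- params$unit_signal * params$expression_scale
  for (i in seq_len(nc)) {
    r0 <- ctr[i, 1]; c0 <- ctr[i, 2]
    # nucleus: filled ellipse, area U(2000, 5000) px
    area <- runif(1, 2000, 5000)
    ecc <- runif(1, 0.7, 1)
    a <- sqrt(area / (pi * ecc)); b <- a * ecc
    rot <- runif(1, 0, pi)
    rlo <- max(1, round(r0 - a - 2)); rhi <- min(H, round(r0 + a + 2))
    clo <- max(1, round(c0 - a - 2)); chi <- min(W, round(c0 + a + 2))
    rr <- rlo:rhi; cc <- clo:chi
    dx <- outer(rr - r0, rep(1, length(cc)))
    dy <- outer(rep(1, length(rr)), cc - c0)
    u <- dx * cos(rot) + dy * sin(rot)
    v <- -dx * sin(rot) + dy * cos(rot)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    hoe[rr, cc][inside] <- hoe[rr, cc][inside] + rnorm(1, 0.55, 0.04)
    centroids <- rbind(centroids, c(r0, c0))
    Rcell <- max(a, b) + runif(1, 25, 40)
    rlo2 <- max(1, round(r0 - Rcell)); rhi2 <- min(H, round(r0 + Rcell))
    clo2 <- max(1, round(c0 - Rcell)); chi2 <- min(W, round(c0 + Rcell))
    rr2 <- rlo2:rhi2; cc2 <- clo2:chi2
    d2 <- outer(rr2 - r0, rep(1, length(cc2)))^2 +
          outer(rep(1, length(rr2)), cc2 - c0)^2
    occ <- d2 <= Rcell^2
    occupancy[rr2, cc2][occ] <- occupancy[rr2, cc2][occ] + 1
    # reticulum: connected perinuclear walks + detached fragments
    ret <- matrix(0, H, W)
    walk <- function(pos, dir, nstep) {
      for (s in seq_len(nstep)) {
        dir <- dir + rnorm(1, 0, 0.35)
        pos <- pos + 2 * c(sin(dir), cos(dir))
        if (sqrt(sum((pos - c(r0, c0))^2)) > Rcell * 0.95)
          dir <- atan2(r0 - pos[1], c0 - pos[2]) + rnorm(1, 0, 0.3)
        pr <- round(pos[1]); pc <- round(pos[2])
        if (pr >= 2 && pr <= H - 1 && pc >= 2 && pc <= W - 1)
          ret[(pr - 1):(pr + 1), (pc - 1):(pc + 1)] <<- 1
      }
    }
    if (params$theta < 1) {
      for (f in 1:6) {
        ang <- runif(1, 0, 2 * pi)
        walk(c(r0 + (b + 3) * sin(ang), c0 + (a + 3) * cos(ang)),
             ang + runif(1, -0.5, 0.5), 150)
      }
      for (f in 1:6) {
        ang <- runif(1, 0, 2 * pi)
        rad <- Rcell * runif(1, 0.72, 0.92)
        walk(c(r0 + rad * sin(ang), c0 + rad * cos(ang)),
             runif(1, 0, 2 * pi), 40)
      }
      npx <- sum(ret)
      if (npx > 0) {
        gfp <- gfp + ret * ((1 - params$theta) * S_unit / npx)
        tot_ret <- tot_ret + (1 - params$theta) * S_unit
      }
    }
    # vesicular puncta in a perinuclear annulus; lognormal brightness
    # heterogeneity (bright puncta become detectable first, giving a
    # graded phenotype onset as theta rises)
    if (params$theta > 0) {
      wts <- exp(rnorm(params$puncta_per_cell, 0, 0.7))
      wts <- wts / sum(wts) * params$theta * S_unit
      for (p in seq_len(params$puncta_per_cell)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, min(b + 4, Rcell * 0.8), Rcell * 0.9)
        gfp <- stamp_gaussian(gfp, r0 + rad * sin(ang),
                              c0 + rad * cos(ang),
                              params$puncta_radius_px, wts[p])
        tot_punct <- tot_punct + wts[p]
      }
    }
  }
  cell_area <- sum(occupancy > 0)
  haze <- if (nc > 0)
    as.matrix(EBImage::gblur(pmin(occupancy, 1), sigma = 30)) *
      params$haze_amp
  else matrix(0, H, W)
  gfp <- gfp + haze + params$background_floor
  gfp <- pmin(pmax(gfp + matrix(rnorm(H * W, 0, params$noise_sd), H, W),
                   0), 1)
  hoe <- hoe + params$background_floor / 2
  hoe <- pmin(pmax(hoe + matrix(rnorm(H * W, 0, params$noise_sd), H, W),
                   0), 1)
  list(gfp = image_field(gfp, "GFP"),
       hoechst = image_field(hoe, "HOECHST"),
       truth = list(n_nuclei = nc, nucleus_centroids = centroids,
                    total_gfp_in_puncta = tot_punct,
                    total_gfp_in_reticulum = tot_ret,
                    cell_mask_area_px = cell_area))
}

#' Render a synthetic filipin field
#'
#' Emulates filipin (unesterified cholesterol) staining: near-zero
#' background, a moderate diffuse cytoplasm, and bright lysosome-like
#' puncta carrying `accum_fraction` of each cell's total filipin
#' signal.  Accumulation scales the *number* of puncta (each punctum
#' keeps a fixed brightness), so the bright population stays separable
#' from the cytoplasm at every accumulation level — the three
#' intensity populations the cluster-based thresholding separates.
#'
#' @param accum_fraction Fraction of per-cell filipin signal in bright
#'   puncta, in `[0,1]`.
#' @param n_cells Cells per field.
#' @param seed Integer seed.
#' @param height,width Field size.
#' @param puncta_per_cell Bright puncta per cell at full accumulation.
#' @param noise_sd Additive Gaussian noise sd.
#' @return List with `filipin` ([image_field()]) and `truth` (list with
#'   `accum_fraction`, `n_cells`, `cell_mask_area_px`).
#' @export
render_filipin_field <- function(accum_fraction, n_cells = 12, seed = 1,
                                 height = 512, width = 512,
                                 puncta_per_cell = 10, noise_sd = 0.01) {
  if (accum_fraction < 0 || accum_fraction > 1)
    stop("render_filipin_field: 'accum_fraction' must lie in [0,1]",
         call. = FALSE)
  set.seed(as.integer(seed))
  H <- height; W <- width
  img <- matrix(0, H, W)
  cellpx <- 0
  S <- 900  # total filipin intensity-sum per cell
  n_p <- round(accum_fraction * puncta_per_cell)
  if (accum_fraction > 0 && n_p == 0) n_p <- 1L
  # mostly non-overlapping cells: overlap would stack the diffuse
  # cytoplasm into spurious bright regions
  ctr <- matrix(NA_real_, n_cells, 2)
  for (i in seq_len(n_cells)) {
    for (try in 1:200) {
      cand <- c(runif(1, 50, H - 50), runif(1, 50, W - 50))
      if (i == 1 || min(sqrt(rowSums(
            (ctr[seq_len(i - 1), , drop = FALSE] -
             matrix(cand, i - 1, 2, byrow = TRUE))^2))) > 85) break
    }
    ctr[i, ] <- cand
  }
  for (i in seq_len(n_cells)) {
    r0 <- ctr[i, 1]; c0 <- ctr[i, 2]
    Rcell <- runif(1, 35, 55)
    rlo <- max(1, round(r0 - Rcell)); rhi <- min(H, round(r0 + Rcell))
    clo <- max(1, round(c0 - Rcell)); chi <- min(W, round(c0 + Rcell))
    rr <- rlo:rhi; cc <- clo:chi
    d2 <- outer(rr - r0, rep(1, length(cc)))^2 +
          outer(rep(1, length(rr)), cc - c0)^2
    body <- d2 <= Rcell^2
    npx <- sum(body)
    cellpx <- cellpx + npx
    # diffuse cytoplasm carries (1 - accum_fraction) of the signal,
    # on a faint shape floor so the cell stays visible at fraction 1;
    # overlaps take the max (a monolayer does not stack)
    diffuse <- (1 - accum_fraction) * S / npx
    img[rr, cc][body] <- pmax(img[rr, cc][body], 0.08 + diffuse)
    if (n_p > 0) {
      per_p <- accum_fraction * S / n_p
      for (p in seq_len(n_p)) {
        ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, Rcell * 0.8)
        img <- stamp_gaussian(img, r0 + rad * sin(ang),
                              c0 + rad * cos(ang), 4, per_p)
      }
    }
  }
  img <- pmin(pmax(img + matrix(rnorm(H * W, 0, noise_sd), H, W), 0), 1)
  list(filipin = image_field(img, "FILIPIN"),
       truth = list(accum_fraction = accum_fraction, n_cells = n_cells,
                    cell_mask_area_px = cellpx))
}

#' Deterministic per-field seed
#'
#' FNV-1a hash of `(master_seed, plate, well, field)` folded into a
#' positive 31-bit integer, so any subset of a plate can be regenerated
#' independently of the rest.
#'
#' @param master_seed Integer master seed.
#' @param plate,well Plate and well identifiers.
#' @param field Field index.
#' @return A positive integer seed.
#' @export
field_seed <- function(master_seed, plate, well, field) {
  key <- paste(master_seed, plate, well, field, sep = "|")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1)) + 1L
}

#' Generate a full synthetic plate set from a layout
#'
#' Renders every field of the layout.  For each well, `theta` comes
#' from the treatment's dose-response model ([theta_from_dose()]),
#' `expression_scale` is `1 + expr_gain * hill_fraction(dose)`, and the
#' expected cell count is reduced by the toxicity survival factor
#' `tox_dose_uM / (dose + tox_dose_uM)` (binomially thinned).  Vehicle
#' and blank wells must map to a zero-effect model (see
#' [null_model()]).  Images are written as 16-bit TIFFs at the paths of
#' the layout and a ground-truth table is returned (and written as
#' CSV).  Per-field seeds derive from [field_seed()], so two runs with
#' the same master seed are identical.
#'
#' @param layout A [plate_layout()] whose `path` column gives the
#'   output TIFF locations (relative to `dir`).
#' @param models Named list mapping every treatment to a
#'   [dose_response_model()].
#' @param base A [phenotype_params()] carrying the field geometry.
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @param truth_csv Optional path for the ground-truth CSV (default
#'   `dir/truth.csv`).
#' @return Invisibly, the ground-truth `data.frame` (one row per
#'   field).
#' @export
generate_plate <- function(layout, models, base = phenotype_params(),
                           seed = 1, dir = ".",
                           truth_csv = file.path(dir, "truth.csv")) {
  stopifnot(inherits(layout, "plate_layout"))
  tr <- unique(layout$treatment)
  missing_models <- setdiff(tr, names(models))
  if (length(missing_models))
    stop("generate_plate: no dose-response model for treatment(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gf <- layout[layout$channel == "GFP", ]
  truth <- NULL
  for (k in seq_len(nrow(gf))) {
    row <- gf[k, ]
    model <- models[[row$treatment]]
    th <- theta_from_dose(row$dose_uM, model)
    hf <- hill_fraction(row$dose_uM, model)
    expr <- 1 + model$expr_gain * hf
    surv <- if (is.finite(model$tox_dose_uM))
      model$tox_dose_uM / (row$dose_uM + model$tox_dose_uM) else 1
    fs <- field_seed(seed, row$plate, row$well, row$field)
    set.seed(fs)
    ncell <- if (surv < 1) rbinom(1, base$n_cells, surv) else base$n_cells
    p <- base
    p$theta <- th; p$expression_scale <- expr; p$n_cells <- ncell
    fld <- render_field(p, height = 512, width = 512, seed = fs + 1L)
    write_field_image(fld$gfp, file.path(dir, row$path))
    hrow <- layout[layout$plate == row$plate & layout$well == row$well &
                   layout$field == row$field & layout$channel == "HOECHST", ]
    if (nrow(hrow) == 1)
      write_field_image(fld$hoechst, file.path(dir, hrow$path))
    truth <- rbind(truth, data.frame(
      plate = row$plate, well = row$well, field = row$field,
      theta = th, expression_scale = expr, n_nuclei = fld$truth$n_nuclei,
      total_gfp_in_puncta = fld$truth$total_gfp_in_puncta,
      total_gfp_in_reticulum = fld$truth$total_gfp_in_reticulum,
      cell_mask_area_px = fld$truth$cell_mask_area_px,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(truth, truth_csv, row.names = FALSE)
  invisible(truth)
}
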