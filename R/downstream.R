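#' Filipin intensity thresholds by 1-D clustering
#'
#' Pools a seeded random subsample of pixel intensities across
#' filipin-stained images and partitions it into `k = 3` clusters by
#' one-dimensional k-means with deterministic initialization: Lloyd
#' iterations are run from evenly spaced sample quantiles, from
#' range-spaced points, and from tail quantiles (rare bright
#' populations are missed by quantile seeding alone), keeping the
#' solution with the lowest within-cluster squared error.  The
#' three cluster means correspond to background, within-cell diffuse
#' signal, and bright lysosome-like puncta; the lower/higher thresholds
#' are the midpoints between consecutive cluster means.
#'
#' @param images List of FILIPIN [image_field()]s (or matrices).
#' @param k Number of intensity populations (3).
#' @param subsample Number of pixels to pool (at least `10 * k`).
#' @param seed Integer seed for the subsample.
#' @return Object of class `filipin_thresholds`: `cluster_means`
#'   (ascending), `lower_threshold`, `higher_threshold`.
#' @export
filipin_cluster_thresholds <- function(images, k = 3, subsample = 50000,
                                       seed = 1) {
  if (!length(images))
    stop("filipin_cluster_thresholds: need at least one image",
         call. = FALSE)
  if (subsample < 10 * k)
    stop("filipin_cluster_thresholds: 'subsample' must be >= 10 * k",
         call. = FALSE)
  px <- unlist(lapply(images, field_pixels,
                      what = "filipin_cluster_thresholds"))
  set.seed(as.integer(seed))
  if (length(px) > subsample) px <- sample(px, subsample)
  if (length(unique(px)) < k)
    stop("filipin_cluster_thresholds: fewer than ", k,
         " distinct intensities (degenerate clustering)", call. = FALSE)
  rng <- range(px)
  inits <- list(
    stats::quantile(px, probs = (seq_len(k) - 0.5) / k, names = FALSE),
    rng[1] + (seq_len(k) - 0.5) / k * diff(rng),
    stats::quantile(px, probs = c(0.02, 0.5, 0.98)[seq_len(k)],
                    names = FALSE))
  best <- NULL
  for (centres in inits) {
    centres <- centres + seq(0, 1e-9, length.out = k)  # keep distinct
    km <- suppressWarnings(
      stats::kmeans(px, centers = matrix(centres, ncol = 1),
                    iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  mu <- sort(as.numeric(best$centers))
  structure(list(cluster_means = mu,
                 lower_threshold = (mu[1] + mu[2]) / 2,
                 higher_threshold = (mu[2] + mu[3]) / 2),
            class = "filipin_thresholds")
}

validate_filipin_thresholds <- function(t) {
  if (!inherits(t, "filipin_thresholds"))
    stop("expected a 'filipin_thresholds' object", call. = FALSE)
  mu <- t$cluster_means
  ok <- length(mu) == 3 && !is.unsorted(mu) &&
    mu[1] < t$lower_threshold && t$lower_threshold < mu[2] &&
    mu[2] < t$higher_threshold && t$higher_threshold < mu[3]
  if (!ok)
    stop("invalid filipin thresholds: need background mean < lower ",
         "threshold < cell mean < higher threshold < puncta mean",
         call. = FALSE)
  invisible(t)
}

#' Relative filipin intensity of one field
#'
#' Cholesterol-accumulation score: the fraction of total in-cell
#' filipin intensity that lies within bright, lysosome-like puncta.
#' The cell region is `pixels > lower_threshold` after a light disc
#' mean filter (diameter 3) that suppresses salt noise; the puncta
#' region is `pixels > higher_threshold` within the cell region.  An
#' image with an empty cell region yields `NaN` with a flag.
#'
#' @param img FILIPIN [image_field()] (or matrix).
#' @param thresholds A `filipin_thresholds` object.
#' @return List of class `filipin_result`: `relative_filipin`,
#'   `cell_area_px`, `puncta_area_px`, `flag`.
#' @export
relative_filipin_intensity <- function(img, thresholds) {
  validate_filipin_thresholds(thresholds)
  x <- field_pixels(img, what = "relative_filipin_intensity")
  disc <- EBImage::makeBrush(3, shape = "disc")
  sm <- as.matrix(EBImage::filter2(x, disc / sum(disc),
                                   boundary = "replicate"))
  cells <- sm > thresholds$lower_threshold
  if (!any(cells))
    return(structure(list(relative_filipin = NaN, cell_area_px = 0L,
                          puncta_area_px = 0L, flag = "no_cells"),
                     class = "filipin_result"))
  puncta <- cells & (sm > thresholds$higher_threshold)
  structure(list(
    relative_filipin = sum(x[puncta]) / sum(x[cells]),
    cell_area_px = sum(cells), puncta_area_px = sum(puncta),
    flag = "ok"), class = "filipin_result")
}

#' Per-image colocalization of two channels
#'
#' Correlation of GFP and marker (e.g., LAMP1) intensities over the
#' in-cell pixels of one image — the per-image statistic summarized per
#' treatment group in colocalization experiments.  Pearson by default;
#' Spearman via `method`.
#'
#' @param gfp,marker The two [image_field()]s (equal size).
#' @param cells Logical cell mask covering at least 100 px.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation in `[-1, 1]`, or `NaN` if either channel has
#'   zero variance within the mask.
#' @export
coloc_correlation <- function(gfp, marker, cells,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  gx <- field_pixels(gfp, what = "coloc_correlation")
  mx <- field_pixels(marker, what = "coloc_correlation")
  if (!identical(dim(gx), dim(mx)) || !identical(dim(gx), dim(cells)))
    stop("coloc_correlation: image and mask shapes differ", call. = FALSE)
  if (sum(cells) < 100)
    stop("coloc_correlation: cell mask must cover at least 100 px",
         call. = FALSE)
  a <- gx[cells]; b <- mx[cells]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NaN)
  stats::cor(a, b, method = method)
}

# Dunn's rank-sum z statistics for all pairwise comparisons, with tie
# correction; p-values are two-sided normal tails.
dunn_pairwise <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  gs <- names(rbar)
  out <- NULL
  for (i in seq_along(gs)) for (j in seq_len(i - 1)) {
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / ns[i] + 1 / ns[j]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    out <- rbind(out, data.frame(
      group1 = gs[i], group2 = gs[j], z = z,
      p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE))
  }
  out
}

#' Group comparison of per-image statistics
#'
#' Two testing routes used with image-level measurements:
#'
#' * `"kruskal_dunn_bh"`: Kruskal-Wallis omnibus rank test followed by
#'   Dunn's pairwise z comparisons with Benjamini-Hochberg adjustment —
#'   the nonparametric route used for colocalization coefficients.
#' * `"dunnett"`: Dunnett's two-sided multiple comparison against a
#'   named control group (single-step adjusted p from multivariate-t
#'   integration), with Shapiro-Wilk normality and Bartlett
#'   variance-homogeneity checks reported alongside (reported, not
#'   enforced as gates) — the parametric route used for relative
#'   filipin intensities.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups,
#'   >= 3 values each).
#' @param method `"kruskal_dunn_bh"` or `"dunnett"`.
#' @param control Name of the control group (dunnett only; default
#'   first group).
#' @return A list of class `group_comparison`; for the rank route:
#'   `omnibus_p`, `pairwise` (with `p_adj`); for dunnett:
#'   `shapiro_p`, `bartlett_p`, `comparisons`.
#' @export
compare_groups <- function(values_by_group,
                           method = c("kruskal_dunn_bh", "dunnett"),
                           control = NULL) {
  method <- match.arg(method)
  if (length(values_by_group) < 2)
    stop("compare_groups: need at least 2 groups", call. = FALSE)
  ns <- lengths(values_by_group)
  if (any(ns < 3))
    stop("compare_groups: every group needs at least 3 values",
         call. = FALSE)
  values <- unlist(values_by_group, use.names = FALSE)
  groups <- factor(rep(names(values_by_group), ns),
                   levels = names(values_by_group))
  if (length(unique(values)) == 1)
    stop("compare_groups: all values identical; tests undefined",
         call. = FALSE)
  if (method == "kruskal_dunn_bh") {
    kw <- stats::kruskal.test(values, groups)
    pw <- dunn_pairwise(values, groups)
    pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
    structure(list(method = method,
                   omnibus_p = kw$p.value,
                   omnibus_statistic = unname(kw$statistic),
                   pairwise = pw),
              class = "group_comparison")
  } else {
    if (is.null(control)) control <- names(values_by_group)[1]
    if (!control %in% names(values_by_group))
      stop("compare_groups: unknown control group '", control, "'",
           call. = FALSE)
    groups <- stats::relevel(groups, ref = control)
    shapiro_p <- tryCatch(
      stats::shapiro.test(stats::residuals(stats::aov(values ~ groups)))$p.value,
      error = function(e) NA_real_)
    bartlett_p <- stats::bartlett.test(values, groups)$p.value
    fit <- stats::aov(values ~ groups)
    glt <- multcomp::glht(fit, linfct = multcomp::mcp(groups = "Dunnett"))
    sm <- summary(glt)  # single-step adjusted, two-sided
    comparisons <- data.frame(
      comparison = names(sm$test$coefficients),
      estimate = unname(sm$test$coefficients),
      p_adj = unname(sm$test$pvalues),
      stringsAsFactors = FALSE)
    structure(list(method = method, control = control,
                   shapiro_p = shapiro_p, bartlett_p = bartlett_p,
                   comparisons = comparisons),
              class = "group_comparison")
  }
}
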