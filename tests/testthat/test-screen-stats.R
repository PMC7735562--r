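test_that("robust Z reproduces the hand-computed oracle", {
  # values {1,2,3,4,100}: median 3, raw MAD 1 -> z(100) = 97/1.4826
  z <- robust_z(c(1, 2, 3, 4, 100))
  expect_equal(z[5], 97 / 1.4826, tolerance = 1e-12)
  expect_identical(z[3], 0)                  # the median maps to 0
  expect_equal(robust_z(c(1, 2, 3, 4, 100), mad_constant = 1)[5], 97)
  expect_error(robust_z(rep(5, 10)), "degenerate")
  expect_error(robust_z(c(1, 2, 3)), "at least 4")
  # NaN propagates without affecting median/MAD
  z2 <- robust_z(c(1, 2, 3, 4, 100, NaN))
  expect_true(is.na(z2[6]))
  expect_equal(z2[5], 97 / 1.4826, tolerance = 1e-12)
})

test_that("robust Z is affine-invariant and centres every plate", {
  set.seed(31)
  for (k in 1:10) {
    x <- rnorm(24, sd = runif(1, 0.5, 3))
    a <- runif(1, 0.1, 5); b <- runif(1, -10, 10)
    expect_equal(robust_z(a * x + b), robust_z(x), tolerance = 1e-9)
    z <- robust_z(x)
    expect_lt(abs(median(z)), 1e-12)
    expect_equal(median(abs(z)) * 1.4826, 1, tolerance = 1e-9)
  }
})

test_that("normalize_features centres each plate on its null wells", {
  set.seed(8)
  rec <- data.frame(
    plate = rep(c("P1", "P2"), each = 12),
    well = rep(sprintf("A%02d", 1:12), 2),
    treatment = "veh", dose_uM = 0,
    role = rep(c(rep("vehicle", 10), "positive_control",
                 "marginal_positive"), 2),
    circularity = runif(24, 0.3, 0.5),
    small_obj_ratio = runif(24, 0, 0.1),
    gfp_int = runif(24, 0.2, 0.4),
    npc1_area_px = 1, cell_area_px = 1, n_nuclei = 10,
    mean_nuc_area_px = 3000, n_objects = 10, n_valid_fields = 6L,
    qc_flag = "ok", stringsAsFactors = FALSE)
  nz <- normalize_features(rec)
  for (p in c("P1", "P2")) {
    centre <- nz$plate == p & nz$role == "vehicle"
    expect_lt(abs(median(nz$robust_z_circularity[centre])), 1e-12)
  }
  expect_identical(attr(nz, "mad_constant"), 1.4826)
  # control wells are normalized but do not shift the centre
  rec2 <- rec
  rec2$circularity[rec2$role == "positive_control"] <- 5
  nz2 <- normalize_features(rec2)
  expect_equal(nz$robust_z_circularity[rec$role == "vehicle"],
               nz2$robust_z_circularity[rec2$role == "vehicle"])
})

test_that("Z' factor follows its closed form and conventions", {
  # means 0 and 10, sds 1 and 1 -> 1 - 6/10
  set.seed(1)
  pos <- c(9, 10, 11); neg <- c(-1, 0, 1)  # sd = 1 exactly
  expect_equal(z_prime(pos, neg), 0.4)
  expect_equal(z_prime(neg, pos), 0.4)     # symmetric in group order
  expect_identical(z_prime(c(1, 1), c(1, 1)), -Inf)
  expect_identical(z_prime(c(5, 5), c(1, 1)), 1)  # zero sds, upper bound
  expect_error(z_prime(1, c(1, 2)), "at least 2")
  for (k in 1:10)
    expect_lte(z_prime(rnorm(8), rnorm(8)), 1)
})

test_that("threshold calibration takes per-feature medians", {
  mk <- function(circ, sor, gi, role = "marginal_positive",
                 qc = "ok") {
    data.frame(plate = "P1", well = paste0("W", seq_along(circ)),
               treatment = "mo56HC", dose_uM = 0.03, role = role,
               qc_flag = qc,
               robust_z_circularity = circ,
               robust_z_small_obj_ratio = sor,
               robust_z_gfp_int = gi, stringsAsFactors = FALSE)
  }
  t <- calibrate_thresholds(mk(c(3.9, 4.03, 4.2), c(4, 4.01, 4.5),
                               c(1.4, 1.5, 1.6)))
  expect_equal(t$circularity_t, 4.03)
  expect_equal(t$small_obj_ratio_t, 4.01)
  expect_equal(t$gfp_int_t, 1.5)
  # NaN-featured wells are excluded before the median
  t2 <- calibrate_thresholds(mk(c(3.9, 4.03, 4.2, NaN),
                                c(4, 4.01, 4.5, 1),
                                c(1.4, 1.5, 1.6, 1)))
  expect_equal(t2$circularity_t, 4.03)
  expect_error(calibrate_thresholds(mk(4, 4, 1.5)), "at least 2")
})

test_that("hit calling is strict on all three features and on role", {
  thresholds <- structure(list(circularity_t = 4.03,
                               small_obj_ratio_t = 4.01,
                               gfp_int_t = 1.50, n_wells = 8),
                          class = "hit_thresholds")
  nz <- data.frame(
    plate = "P1", well = c("A01", "A02", "A03", "A04"),
    treatment = c("drugA", "drugB", "veh", "drugC"),
    dose_uM = c(10, 10, 0, 10),
    role = c("library", "library", "vehicle", "library"),
    qc_flag = c("ok", "ok", "ok", "no_objects"),
    robust_z_circularity = c(5.0, 5.0, 9, 8),
    robust_z_small_obj_ratio = c(4.5, 4.5, 9, 8),
    robust_z_gfp_int = c(2.0, 1.50, 9, 8),
    stringsAsFactors = FALSE)
  hits <- call_hits(nz, thresholds)
  expect_true(hits$is_hit[1])                   # exceeds all three
  expect_false(hits$is_hit[2])                  # gfp_int == threshold
  expect_false(hits$is_hit[3])                  # vehicle never a hit
  expect_true(hits$exceeds_all[3])              # ... but reported
  expect_true(hits$excluded[4])                 # qc-flagged excluded
  expect_false(hits$is_hit[4])
})

test_that("the QC report computes per-plate windows and flags degeneracy", {
  set.seed(14)
  mkrow <- function(plate, well, role, dose, circ) {
    data.frame(plate = plate, well = well, treatment = "x",
               dose_uM = dose, role = role, qc_flag = "ok",
               circularity = circ, small_obj_ratio = circ / 2,
               gfp_int = 1, stringsAsFactors = FALSE)
  }
  nz <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      mkrow("P1", paste0("V", i), "vehicle", 0, rnorm(1, 0.4, 0.01)))),
    do.call(rbind, lapply(1:4, function(i)
      mkrow("P1", paste0("C", i), "positive_control", 10,
            rnorm(1, 0.8, 0.01)))))
  rep1 <- qc_report(nz)
  circ_row <- rep1[rep1$feature == "circularity", ]
  expect_equal(circ_row$z_prime,
               z_prime(nz$circularity[5:8], nz$circularity[1:4]))
  expect_false(circ_row$degenerate)
  expect_identical(circ_row$n_pos, 4L)
  # gfp_int identical in both groups -> -Inf sentinel, flagged
  gfp_row <- rep1[rep1$feature == "gfp_int", ]
  expect_identical(gfp_row$z_prime, -Inf)
  expect_true(gfp_row$degenerate)
})

test_that("dose-response summaries use sample SD and omit empty doses", {
  nz <- data.frame(
    plate = "P1", well = sprintf("A%02d", 1:5),
    treatment = c(rep("mo56HC", 3), "mo56HC", "other"),
    dose_uM = c(0.3, 0.3, 1, 3, 1),
    role = "positive_control", qc_flag = "ok",
    robust_z_circularity = c(0.2, 0.4, 2, 5, 0),
    robust_z_small_obj_ratio = 1, robust_z_gfp_int = 1,
    stringsAsFactors = FALSE)
  s <- dose_response_summary(nz, "mo56HC")
  r <- s[s$dose_uM == 0.3 & s$feature == "circularity", ]
  expect_equal(r$mean, 0.3)
  expect_equal(r$sd, sd(c(0.2, 0.4)))
  expect_identical(r$n, 2L)
  single <- s[s$dose_uM == 1 & s$feature == "circularity", ]
  expect_true(is.na(single$sd))
  expect_identical(sort(unique(s$dose_uM)), c(0.3, 1, 3))
  expect_error(dose_response_summary(nz, "nope"), "no wells")
})
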