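test_that("circularity matches analytic shape oracles", {
  fcfg <- feature_config()
  disc <- label_mask(mk_disc_mask(201, 50.2, 101), 8)
  expect_gte(circularity(disc, fcfg), 0.95)
  expect_lte(circularity(disc, fcfg), 1)

  sq <- label_mask(mk_rect_mask(120, 120, 100, 100), 8)
  expect_equal(circularity(sq, fcfg), pi / 4, tolerance = 0.05 / (pi / 4))

  line <- label_mask(mk_rect_mask(10, 220, 1, 200, 5, 10), 8)
  expect_lt(circularity(line, fcfg), 0.1)

  expect_true(is.nan(circularity(label_mask(matrix(FALSE, 64, 64), 8))))
})

test_that("per-object circularity matches brute-force enumeration on a small-shape library", {
  # every <= 20x20 shape: area by pixel count, perimeter by the
  # analytic rectangle-cycle oracle (axis-aligned shapes only)
  fcfg <- feature_config()
  shapes <- list(c(4, 4), c(2, 10), c(1, 15), c(7, 3), c(20, 20))
  for (dims in shapes) {
    mask <- mk_rect_mask(dims[1] + 12, dims[2] + 12, dims[1], dims[2], 6, 6)
    lm <- label_mask(mask, 8)
    expect_identical(object_areas(lm), as.integer(prod(dims)))
    expected <- min(1, 4 * pi * prod(dims) /
                         rect_smoothed_perimeter(dims[1], dims[2])^2)
    expect_equal(circularity(lm, fcfg), expected, tolerance = 1e-10,
                 info = paste(dims, collapse = "x"))
  }
})

test_that("small-object ratio follows its worked examples and bounds", {
  fcfg <- feature_config(small_obj_area_px = 500)
  # objects of areas 100 and 900 -> 100/1000 = 0.1
  m <- matrix(FALSE, 80, 80)
  m[2:11, 2:11] <- TRUE      # 100 px
  m[31:60, 31:60] <- TRUE    # 900 px
  lm <- label_mask(m, 8)
  expect_equal(small_obj_ratio(lm, fcfg), 0.1)

  small_only <- label_mask(mk_rect_mask(30, 30, 5, 5), 8)
  expect_identical(small_obj_ratio(small_only, fcfg), 1)
  big_only <- label_mask(mk_rect_mask(80, 80, 30, 30), 8)
  expect_identical(small_obj_ratio(big_only, fcfg), 0)
  # strict inequality at the threshold: area exactly 500 is not small
  at_t <- label_mask(mk_rect_mask(60, 60, 20, 25), 8)
  expect_identical(small_obj_ratio(at_t, fcfg), 0)
  expect_true(is.nan(small_obj_ratio(label_mask(matrix(FALSE, 64, 64), 8),
                                     fcfg)))
})

test_that("GFP intensity per cell area is plain arithmetic", {
  img <- matrix(0, 64, 64)
  img[2:11, 2:11] <- 0.5                 # pattern sums to 50
  lm <- label_mask(img > 0, 8)
  cells <- matrix(FALSE, 64, 64)
  cells[1:40, 1:25] <- TRUE              # 1000 px
  expect_equal(gfp_int(img, lm, cells), 0.05)
  # empty pattern, non-empty mask -> 0; linearity under doubling
  expect_identical(gfp_int(img, label_mask(matrix(FALSE, 64, 64), 8),
                           cells), 0)
  expect_equal(gfp_int(img * 2, lm, cells), 0.1)
  expect_true(is.nan(gfp_int(img, lm, matrix(FALSE, 64, 64))))
})

test_that("shape features are invariant to gain and rotation", {
  fcfg <- feature_config()
  cfg <- screen_config()
  # clean fixture: bright discs and a bar on black, away from borders
  img <- matrix(0, 320, 320)
  img[mk_disc_mask(320, 9, 100)] <- 0.6
  d2 <- outer(seq_len(320) - 220, seq_len(320) - 220,
              function(a, b) a^2 + b^2)
  img[d2 <= 81] <- 0.6
  img[150:153, 60:200] <- 0.6
  feats <- function(m) {
    patt <- extract_gfp_pattern(image_field(m, "GFP"), cfg)
    c(circularity(patt, fcfg), small_obj_ratio(patt, fcfg))
  }
  base <- feats(img)
  # uniform gain above threshold-stability
  expect_equal(feats(img * 0.8), base, tolerance = 1e-6)
  expect_equal(feats(pmin(img * 1.2, 1)), base, tolerance = 1e-6)
  # 90-degree rotation
  expect_equal(feats(t(img[nrow(img):1, ])), base, tolerance = 1e-6)
})

test_that("punctate fields score higher than reticular fields", {
  scfg <- screen_config(); fcfg <- feature_config()
  lo <- NULL; hi <- NULL
  for (s in 1:8) {
    p_lo <- phenotype_params(theta = 0.1, n_cells = 10)
    p_hi <- phenotype_params(theta = 0.9, n_cells = 10)
    f_lo <- render_field(p_lo, 384, 384, seed = 400 + s)
    f_hi <- render_field(p_hi, 384, 384, seed = 400 + s)
    lo <- rbind(lo, compute_field_features(f_lo$gfp, f_lo$hoechst,
                                           scfg, fcfg))
    hi <- rbind(hi, compute_field_features(f_hi$gfp, f_hi$hoechst,
                                           scfg, fcfg))
  }
  expect_gt(median(hi$circularity), median(lo$circularity))
  expect_gt(median(hi$small_obj_ratio), median(lo$small_obj_ratio))
})

test_that("blank fields are flagged and aggregation follows the rules", {
  scfg <- screen_config(); fcfg <- feature_config()
  # noise at the instrument level: a cell-free blank must yield no
  # detected objects
  blank <- render_field(phenotype_params(theta = 0, n_cells = 0,
                                         noise_sd = 0.005),
                        height = 256, width = 256, seed = 9)
  ff <- compute_field_features(blank$gfp, blank$hoechst, scfg, fcfg)
  expect_identical(ff$n_objects, 0L)
  expect_identical(ff$qc, "no_objects")
  expect_true(is.nan(ff$circularity))

  meta <- list(plate = "P1", well = "A01", treatment = "veh",
               dose_uM = 0, role = "vehicle")
  f1 <- data.frame(circularity = c(0.2, 0.4),
                   small_obj_ratio = c(0.1, 0.3),
                   gfp_int = c(0.3, 0.5), npc1_area_px = c(100, 200),
                   cell_area_px = c(1000, 1000), n_nuclei = c(10, 12),
                   mean_nuc_area_px = c(3000, 3100), n_objects = c(5, 7),
                   qc = "ok", stringsAsFactors = FALSE)
  rec <- aggregate_well(f1, meta, fcfg)
  expect_equal(rec$circularity, 0.3)
  expect_identical(rec$n_valid_fields, 2L)
  expect_identical(rec$qc_flag, "no_objects")  # < 3 valid fields

  # six identical fields reproduce the field values
  f6 <- f1[rep(1, 6), ]
  rec6 <- aggregate_well(f6, meta, fcfg)
  expect_equal(rec6$circularity, 0.2)
  expect_identical(rec6$qc_flag, "ok")

  # NaN-feature fields excluded from shape means, not from counts
  fmix <- rbind(f1[rep(1, 3), ],
                data.frame(circularity = NaN, small_obj_ratio = NaN,
                           gfp_int = NaN, npc1_area_px = 0,
                           cell_area_px = 900, n_nuclei = 2,
                           mean_nuc_area_px = NaN, n_objects = 0,
                           qc = "no_objects", stringsAsFactors = FALSE))
  recm <- aggregate_well(fmix, meta, fcfg)
  expect_equal(recm$circularity, 0.2)
  expect_equal(recm$n_nuclei, mean(c(10, 10, 10, 2)))
  expect_error(aggregate_well(f1[0, ], meta, fcfg), "at least one")
})
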