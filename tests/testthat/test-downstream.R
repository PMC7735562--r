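test_that("filipin clustering recovers three well-separated populations", {
  set.seed(21)
  mkimg <- function() {
    n <- 96 * 96
    pop <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
    mu <- c(0.05, 0.30, 0.80)[pop]
    matrix(pmin(pmax(rnorm(n, mu, 0.02), 0), 1), 96, 96)
  }
  imgs <- lapply(1:3, function(i) image_field(mkimg(), "FILIPIN"))
  t <- filipin_cluster_thresholds(imgs, subsample = 20000, seed = 5)
  expect_equal(t$cluster_means, c(0.05, 0.30, 0.80), tolerance = 0.02 / 0.05)
  expect_equal(t$lower_threshold, 0.175, tolerance = 0.1)
  expect_equal(t$higher_threshold, 0.55, tolerance = 0.05)
  # determinism
  t2 <- filipin_cluster_thresholds(imgs, subsample = 20000, seed = 5)
  expect_identical(t$cluster_means, t2$cluster_means)
  # degenerate input
  const <- list(image_field(matrix(0.5, 64, 64), "FILIPIN"))
  expect_error(filipin_cluster_thresholds(const), "degenerate")
})

test_that("quantile-seeded clustering matches the exhaustive 1-D oracle", {
  set.seed(33)
  for (rep in 1:5) {
    x <- c(rnorm(400, 0.05, 0.02), rnorm(300, 0.3, 0.03),
           rnorm(120, 0.8, 0.03))
    x <- pmin(pmax(x, 0), 1)
    img <- image_field(matrix(rep_len(x, 64 * 64), 64, 64), "FILIPIN")
    t <- filipin_cluster_thresholds(list(img), subsample = 64 * 64,
                                    seed = rep)
    oracle <- kmeans1d_optimal(img$pixels, 3)
    expect_equal(t$cluster_means, oracle, tolerance = 1e-6,
                 info = paste("rep", rep))
  }
})

test_that("relative filipin intensity has the stated limits and gain invariance", {
  # thresholds placed so the smoothing filter's soft edges stay inside
  # the puncta region: the bright block then carries all in-cell signal
  t <- structure(list(cluster_means = c(0.01, 0.1, 0.8),
                      lower_threshold = 0.055, higher_threshold = 0.35),
                 class = "filipin_thresholds")
  # all in-cell signal in puncta pixels -> 1
  img <- matrix(0, 64, 64); img[20:40, 20:40] <- 0.9
  r <- relative_filipin_intensity(img, t)
  expect_equal(r$relative_filipin, 1, tolerance = 1e-6)
  # nothing above the higher threshold -> 0
  img2 <- matrix(0, 64, 64); img2[20:40, 20:40] <- 0.3
  expect_identical(relative_filipin_intensity(img2, t)$relative_filipin, 0)
  # empty cell region -> NaN + flag
  r3 <- relative_filipin_intensity(matrix(0.01, 64, 64), t)
  expect_true(is.nan(r3$relative_filipin))
  expect_identical(r3$flag, "no_cells")
  # joint gain invariance (image and thresholds scaled together)
  img4 <- matrix(0.02, 64, 64)
  img4[10:30, 10:30] <- 0.28; img4[15:18, 15:18] <- 0.9
  a <- 0.7
  ta <- structure(list(cluster_means = t$cluster_means * a,
                       lower_threshold = t$lower_threshold * a,
                       higher_threshold = t$higher_threshold * a),
                  class = "filipin_thresholds")
  expect_equal(relative_filipin_intensity(img4, t)$relative_filipin,
               relative_filipin_intensity(img4 * a, ta)$relative_filipin,
               tolerance = 1e-9)
  bad <- structure(list(cluster_means = c(0.3, 0.2, 0.8),
                        lower_threshold = 0.25, higher_threshold = 0.5),
                   class = "filipin_thresholds")
  expect_error(relative_filipin_intensity(img, bad), "invalid")
})

test_that("accumulation recovery is monotone in the generated fraction", {
  med <- vapply(c(0.1, 0.5, 0.9), function(af) {
    vals <- vapply(1:10, function(s) {
      f <- render_filipin_field(af, n_cells = 8, seed = 600 + s,
                                height = 320, width = 320)
      t <- filipin_cluster_thresholds(list(f$filipin),
                                      subsample = 40000, seed = s)
      relative_filipin_intensity(f$filipin, t)$relative_filipin
    }, 0)
    median(vals)
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("colocalization correlation obeys its identities", {
  set.seed(17)
  g <- matrix(runif(128 * 128), 128, 128)
  cells <- matrix(TRUE, 128, 128)
  expect_equal(coloc_correlation(g, g, cells), 1)
  expect_equal(coloc_correlation(g, 1 - g, cells), -1)
  h <- matrix(runif(128 * 128), 128, 128)
  expect_lt(abs(coloc_correlation(g, h, cells)), 0.05)
  # symmetry and positive-affine invariance
  expect_equal(coloc_correlation(g, h, cells),
               coloc_correlation(h, g, cells))
  expect_equal(coloc_correlation(g, pmin(0.5 * h + 0.2, 1), cells),
               coloc_correlation(g, h, cells), tolerance = 1e-9)
  expect_true(is.nan(coloc_correlation(g, matrix(0.5, 128, 128), cells)))
  expect_error(coloc_correlation(g, h, matrix(FALSE, 128, 128)),
               "100 px")
})

test_that("rank-based group comparison controls type I error", {
  pvals <- vapply(1:20, function(s) {
    set.seed(700 + s)
    vals <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    compare_groups(vals, "kruskal_dunn_bh")$omnibus_p
  }, 0)
  expect_gte(sum(pvals > 0.05), 18)
})

test_that("Dunnett comparison detects a large effect and reports checks", {
  set.seed(99)
  vals <- list(control = rnorm(10), treated = rnorm(10, 3))
  r <- compare_groups(vals, "dunnett", control = "control")
  expect_lt(r$comparisons$p_adj[1], 0.01)
  expect_true(is.numeric(r$shapiro_p) && is.numeric(r$bartlett_p))
  expect_error(compare_groups(list(a = rep(1, 5), b = rep(1, 5)),
                              "kruskal_dunn_bh"), "identical")
  expect_error(compare_groups(list(a = 1:2, b = 1:5), "dunnett"),
               "at least 3")
})

test_that("Dunn z statistics match the textbook formula and BH is monotone", {
  set.seed(3)
  vals <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  r <- compare_groups(vals, "kruskal_dunn_bh")
  pw <- r$pairwise
  # hand computation for one pair (no ties with continuous data)
  x <- unlist(vals); g <- rep(names(vals), each = 8)
  rk <- rank(x); N <- length(x)
  z_ab <- (mean(rk[g == "b"]) - mean(rk[g == "a"])) /
    sqrt(N * (N + 1) / 12 * (2 / 8))
  row <- pw[(pw$group1 == "b" & pw$group2 == "a") |
            (pw$group1 == "a" & pw$group2 == "b"), ]
  expect_equal(abs(row$z), abs(z_ab), tolerance = 1e-10)
  # BH never decreases p-values and preserves ordering
  expect_true(all(pw$p_adj >= pw$p))
  expect_identical(order(pw$p), order(pw$p_adj))
})
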