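# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's own implementations.

# --- shape fixtures -------------------------------------------------

mk_disc_mask <- function(n, r, ctr = (n + 1) / 2) {
  d2 <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
              function(a, b) a^2 + b^2)
  d2 <= r^2
}

mk_rect_mask <- function(h, w, rect_h, rect_w, r0 = 10, c0 = 10) {
  m <- matrix(FALSE, h, w)
  m[r0:(r0 + rect_h - 1), c0:(c0 + rect_w - 1)] <- TRUE
  m
}

# --- brute-force connected-component labeler (stack flood fill) -----

flood_fill_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nb))) {
          r <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
          if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
              mask[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            stack[[length(stack) + 1L]] <- c(r, cc)
          }
        }
      }
    }
  }
  lab
}

# canonicalize a labeling so two labelings can be compared up to label
# permutation: relabel in order of first (column-major) appearance
canonical_labels <- function(lab) {
  ids <- unique(lab[lab > 0])
  lut <- integer(max(c(ids, 1L)))
  lut[ids] <- seq_along(ids)
  lab[lab > 0] <- lut[lab[lab > 0]]
  lab
}

# --- analytic smoothed-contour perimeter for axis-aligned rectangles
# Builds the marching-squares vertex cycle of an isolated rect_h x
# rect_w rectangle directly (edge midpoints at half-pixel positions,
# counter-clockwise), applies a circular moving average of window w,
# and sums segment lengths.  Fully independent of the package's
# case-table contour tracer.

rect_contour_vertices <- function(rect_h, rect_w) {
  # pixel centers at 1..rect_h x 1..rect_w.  The iso-0.5 contour has
  # one vertex per boundary pixel edge midpoint: along horizontal
  # edges at (r -/+ 0.5, integer c), along vertical edges at
  # (integer r, c -/+ 0.5); corners join with half-diagonal segments.
  top    <- cbind(0.5, seq_len(rect_w))
  right  <- cbind(seq_len(rect_h), rect_w + 0.5)
  bottom <- cbind(rect_h + 0.5, rev(seq_len(rect_w)))
  left   <- cbind(rev(seq_len(rect_h)), 0.5)
  rbind(top, right, bottom, left)
}

rect_smoothed_perimeter <- function(rect_h, rect_w, window = 5) {
  v <- rect_contour_vertices(rect_h, rect_w)
  n <- nrow(v)
  idx <- ((seq_len(n) - 1 + window) %% n) + 1
  sum(sqrt(rowSums((v[idx, , drop = FALSE] - v)^2))) / window
}

# --- exhaustive 1-D k-means oracle (dynamic programming) ------------
# Optimal squared-error partition of sorted 1-D data into k contiguous
# clusters; returns cluster means.  O(k n^2) with prefix sums.

kmeans1d_optimal <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  sse <- function(i, j) {  # cost of cluster x[i..j]
    s <- cs[j + 1] - cs[i]; s2 <- cs2[j + 1] - cs2[i]
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1, j] <- sse(1, j)
  for (m in 2:k) for (j in m:n) {
    i <- m:j
    costs <- D[m - 1, i - 1] + vapply(i, function(ii) sse(ii, j), 0)
    best <- which.min(costs)
    D[m, j] <- costs[best]
    B[m, j] <- i[best]
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  for (m in k:2) bounds[m] <- B[m, bounds[m + 1]] - 1L
  bounds[1] <- 0L
  vapply(seq_len(k), function(m)
    mean(x[(bounds[m] + 1):bounds[m + 1]]), 0)
}

# --- Hoechst-like field with non-touching elliptical nuclei ---------

render_nuclei_field <- function(n_nuclei, height = 480, width = 480,
                                area_range = c(2500, 3500),
                                noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  img <- matrix(0, height, width)
  grid <- expand.grid(r = seq(70, height - 70, by = 130),
                      c = seq(70, width - 70, by = 130))
  stopifnot(nrow(grid) >= n_nuclei)
  pick <- grid[sample(nrow(grid), n_nuclei), , drop = FALSE]
  for (i in seq_len(n_nuclei)) {
    area <- runif(1, area_range[1], area_range[2])
    ecc <- runif(1, 0.8, 1)
    a <- sqrt(area / (pi * ecc)); b <- a * ecc
    r0 <- pick$r[i] + runif(1, -10, 10)
    c0 <- pick$c[i] + runif(1, -10, 10)
    rr <- max(1, round(r0 - a - 2)):min(height, round(r0 + a + 2))
    cc <- max(1, round(c0 - a - 2)):min(width, round(c0 + a + 2))
    dx <- outer(rr - r0, rep(1, length(cc)))
    dy <- outer(rep(1, length(rr)), cc - c0)
    img[rr, cc][(dx / a)^2 + (dy / b)^2 <= 1] <- rnorm(1, 0.55, 0.04)
  }
  img <- pmin(pmax(img + matrix(rnorm(height * width, 0, noise_sd),
                                height, width), 0), 1)
  image_field(img, "HOECHST")
}
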