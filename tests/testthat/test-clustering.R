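test_that("tuning similarity is a correlation with its edge cases", {
  set.seed(1)
  w <- rnorm(50)
  expect_equal(tuning_similarity(w, w), 1)
  expect_equal(tuning_similarity(w, -w), -1)
  chk1 <- rep(c(1, -1), 25)
  chk2 <- rep(c(1, 1, -1, -1), length.out = 50)   # orthogonal, zero-mean
  expect_lt(abs(tuning_similarity(chk1, chk2)), 1e-9)
  expect_error(tuning_similarity(rep(1, 50), w), "constant")
})

test_that("cortical distance projects onto the cortical surface", {
  same <- cortical_distance(c(10, 20, 40), c(10, 20, 40))
  expect_equal(same, list(d_um = 0, delta_depth_um = 0))
  d <- cortical_distance(c(0, 0, 0), c(30, 40, 40))
  expect_equal(d$d_um, 50)
  expect_equal(d$delta_depth_um, 40)
  expect_equal(d, cortical_distance(c(30, 40, 40), c(0, 0, 0)))
})

test_that("orientation differences wrap on the half-circle", {
  expect_equal(orientation_difference(10, 170), 20)
  expect_equal(orientation_difference(0, 90), 90)
  expect_equal(orientation_difference(45, 45), 0)
  set.seed(2)
  a <- runif(100, 0, 180); b <- runif(100, 0, 180)
  d <- orientation_difference(a, b)
  expect_true(all(d >= 0 & d <= 90))
  expect_equal(d, orientation_difference(b, a))
})

test_that("rank-sum p-values are exact for small samples", {
  expect_equal(ranksum_test(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(ranksum_test(c(3, 4), c(1, 2), "greater"), 1 / 6)
  set.seed(3)
  x <- rnorm(200)
  expect_gt(ranksum_test(x, x, "two.sided"), 0.9)
})

test_that("normal approximation tracks exhaustive enumeration", {
  # brute-force null distribution of the rank sum for n = m = 6
  exact_p_less <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    stat <- sum(r[seq_along(x)])
    combos <- utils::combn(12, 6)
    stats <- colSums(matrix(r[combos], nrow = 6))
    mean(stats <= stat)
  }
  set.seed(4)
  worst <- 0
  for (i in 1:25) {
    x <- rnorm(6); y <- rnorm(6, sample(c(0, 1), 1))
    pe <- exact_p_less(x, y)
    pi_ <- ranksum_test(x, y, "less", method = "exact")
    expect_equal(pi_, pe, tolerance = 1e-12)
    pn <- ranksum_test(x, y, "less", method = "normal")
    worst <- max(worst, abs(pn - pe))
  }
  expect_lt(worst, 0.02)
})

test_that("pair tables are symmetric, unique and within-field", {
  set.seed(5)
  cells <- tibble::tibble(
    cell_id = 1:10,
    x_um = runif(10, 0, 200), y_um = runif(10, 0, 200),
    depth_um = rep(c(0, 40), 5),
    pref_orientation_deg = runif(10, 0, 180),
    pref_sf_cpd = 2^rnorm(10, log2(0.04), 0.5)
  )
  W <- matrix(rnorm(40 * 10), 40)
  pt <- pair_table(cells, W)
  expect_equal(nrow(pt), choose(10, 2))
  expect_true(all(pt$cell_i < pt$cell_j))
  expect_true(all(pt$similarity >= -1 & pt$similarity <= 1))
  expect_true(all(pt$d_ori_deg >= 0 & pt$d_ori_deg <= 90))

  # reversing cell order leaves the pair statistics unchanged
  rev_idx <- 10:1
  pt2 <- pair_table(cells[rev_idx, ], W[, rev_idx])
  expect_equal(sort(pt2$similarity), sort(pt$similarity), tolerance = 1e-12)
  expect_equal(sort(pt2$d_um), sort(pt$d_um), tolerance = 1e-12)

  # pairs never span fields
  cells$field <- rep(c("a", "b"), each = 5)
  pt3 <- pair_table(cells, W)
  expect_equal(nrow(pt3), 2 * choose(5, 2))
})

test_that("binned similarity is a partition of the pooled pairs", {
  set.seed(6)
  n <- 500
  pairs <- tibble::tibble(d_um = runif(n, 0, 209),
                          similarity = rnorm(n, 0.2, 0.1))
  class(pairs) <- c("pair_table", class(pairs))
  curve <- bin_similarity(pairs)
  expect_equal(sum(curve$n_pairs), n)
  pooled <- sum(curve$mean * curve$n_pairs) / sum(curve$n_pairs)
  expect_equal(pooled, mean(pairs$similarity), tolerance = 1e-12)
  expect_equal(curve$ranksum_p_vs_last[nrow(curve)], 1)
  expect_true(all(curve$sem >= 0))

  # constant similarity: all means equal, no bin significant
  pairs$similarity <- 0.3
  curve2 <- bin_similarity(pairs)
  expect_true(all(curve2$mean == 0.3))
  expect_true(all(curve2$ranksum_p_vs_last[-nrow(curve2)] > 0.4))
})

test_that("exponential fit recovers noiseless parameters to 1e-6", {
  d <- seq(15, 195, by = 30)
  curve <- tibble::tibble(bin_mid = d, mean = 0.1 + 0.4 * exp(-d / 38))
  class(curve) <- c("similarity_curve", class(curve))
  fit <- fit_exponential_decay(curve, n_boot = 0)
  expect_equal(fit$asymptote, 0.1, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.4, tolerance = 1e-6)
  expect_equal(fit$length_constant_um, 38, tolerance = 1e-6)
  expect_true(fit$identifiable)
})

test_that("flat curves are flagged unidentifiable with a grid-wide CI", {
  curve <- tibble::tibble(bin_mid = seq(15, 195, by = 30), mean = 0.25)
  class(curve) <- c("similarity_curve", class(curve))
  fit <- fit_exponential_decay(curve, n_boot = 0)
  expect_false(fit$identifiable)
  expect_equal(fit$ci95_lambda, c(10, 160))
})

test_that("near/far preference test behaves at its null", {
  set.seed(7)
  pairs <- tibble::tibble(
    d_um = c(runif(300, 0, 49), runif(300, 151, 250)),
    similarity = rnorm(600),
    d_ori_deg = runif(600, 0, 90),
    d_log_sf = abs(rnorm(600))
  )
  class(pairs) <- c("pair_table", class(pairs))
  res <- near_far_preference_test(pairs)
  expect_equal(res$n_near, 300)
  expect_equal(res$n_far, 300)
  expect_gt(res$p, 0.001)    # null data: no systematic effect

  # identical groups: p near one half
  pairs2 <- pairs
  pairs2$d_ori_deg <- rep(seq(0, 90, length.out = 300), 2)
  p2 <- near_far_preference_test(pairs2)$p
  expect_gt(p2, 0.4); expect_lt(p2, 0.6)
  expect_error(near_far_preference_test(pairs[pairs$d_um < 50, ]), "empty")
})

test_that("per-field correlation matches exact and null cases", {
  d <- seq(1, 300, length.out = 50)
  pairs <- tibble::tibble(d_um = d, similarity = 1 - d / 300)
  class(pairs) <- c("pair_table", class(pairs))
  pf <- per_field_correlation(pairs)
  expect_equal(pf$r, -1, tolerance = 1e-12)
  expect_lt(pf$p, 1e-20)

  set.seed(8)
  pairs2 <- tibble::tibble(d_um = runif(1e4, 0, 200), similarity = rnorm(1e4))
  class(pairs2) <- c("pair_table", class(pairs2))
  expect_lt(abs(per_field_correlation(pairs2)$r), 0.05)

  expect_error(per_field_correlation(pairs2[1:2, ]), "3 pairs")
  const <- tibble::tibble(d_um = 1:10, similarity = rep(0.3, 10))
  expect_error(per_field_correlation(const), "zero variance")
})

test_that("depth grouping assigns each pair to exactly one level", {
  set.seed(9)
  pairs <- tibble::tibble(
    d_um = runif(800, 0, 200),
    delta_depth_um = sample(c(0, 40, 80, 120), 800, replace = TRUE),
    similarity = rnorm(800, 0.2)
  )
  class(pairs) <- c("pair_table", class(pairs))
  fam <- depth_similarity_analysis(pairs)
  expect_named(fam, c("delta_0", "delta_40", "delta_80", "delta_120"))
  expect_equal(sum(vapply(fam, function(cv) sum(cv$n_pairs), 0)), 800)
  # a pair at depths 0 and 80 lands only in the delta = 80 group
  one <- pairs[1, ]; one$delta_depth_um <- 80
  expect_equal(sum(bin_similarity(one, c(0, 105, 210))$n_pairs), 1)
})

test_that("robustness filters keep the documented subsets", {
  set.seed(10)
  cells <- tibble::tibble(
    cell_id = 1:100,
    kurtosis = c(rep(20, 70), rep(5, 30)),
    pref_sf_cpd = c(rep(0.05, 60), rep(0.02, 40)),
    roi_area_um2 = sample(100)
  )
  expect_equal(nrow(robustness_filter(cells, "kurtosis_ge_15")), 70)
  expect_equal(nrow(robustness_filter(cells, "peak_sf_gt_0.025")), 60)
  top <- robustness_filter(cells, "roi_top_80pct")
  expect_equal(nrow(top), 80)
  expect_true(min(top$roi_area_um2) > min(cells$roi_area_um2))
  # all-pass filter is the identity
  cells2 <- cells; cells2$kurtosis <- 30
  expect_equal(nrow(robustness_filter(cells2, "kurtosis_ge_15")), 100)
  cells3 <- cells; cells3$kurtosis <- 3
  expect_error(robustness_filter(cells3, "kurtosis_ge_15"), "every cell")
})

test_that("the decay asymptote tracks the shared low-SF bias", {
  # a stronger population-wide low-SF component should raise the fitted
  # asymptote monotonically
  grid <- build_design(toy_sequence(duration_s = 1, sf_max_cpd = 0.15))$grid
  weights <- c(0, 0.15, 0.3, 0.6, 1)
  asymptotes <- vapply(weights, function(wt) {
    cells <- place_cells(sheet_config(interneuron_frac = 0,
                                      low_sf_bias_weight = wt), seed = 21)
    W <- vapply(seq_len(nrow(cells)), function(i) {
      ground_truth_kernel(cells$pref_orientation_deg[i],
                          cells$pref_sf_cpd[i], grid,
                          low_sf_bias_weight = wt)
    }, numeric(nrow(grid)))
    fit_exponential_decay(pair_table(cells, W), n_boot = 0)$asymptote
  }, 0)
  expect_gt(cor(weights, asymptotes, method = "spearman"), 0.9)
})
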