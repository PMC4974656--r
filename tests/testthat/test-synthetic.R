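test_that("salt-and-pepper maps have uniform orientation differences", {
  maps <- generate_preference_maps(400, map_length_um = 0, seed = 1)
  ori <- as.vector(maps$orientation_deg)
  set.seed(2)
  i <- sample(length(ori), 1e4, replace = TRUE)
  j <- sample(length(ori), 1e4, replace = TRUE)
  d <- orientation_difference(ori[i], ori[j])
  expect_gt(mean(d), 42); expect_lt(mean(d), 48)   # uniform mean = 45
})

test_that("smoothed maps make close-by preferences similar", {
  maps <- generate_preference_maps(500, map_length_um = 200,
                                   grid_step_um = 5, seed = 3)
  ori <- maps$orientation_deg
  # pairs < 20 um apart = up to 4 grid steps
  d <- orientation_difference(ori[1:(nrow(ori) - 3), ], ori[4:nrow(ori), ])
  expect_lt(median(d), 15)
})

test_that("preference maps are reproducible and scaled as requested", {
  m1 <- generate_preference_maps(200, 30, seed = 7)
  m2 <- generate_preference_maps(200, 30, seed = 7)
  expect_identical(m1, m2)
  m3 <- generate_preference_maps(200, 30, seed = 8)
  expect_false(identical(m1$orientation_deg, m3$orientation_deg))
  expect_true(all(m1$orientation_deg >= 0 & m1$orientation_deg < 180))
  expect_equal(mean(m1$log2_sf), log2(0.04), tolerance = 1e-9)
  expect_equal(sd(m1$log2_sf), 0.5, tolerance = 1e-9)
})

test_that("cell placement respects soma exclusion and plane structure", {
  cfg <- sheet_config(n_cells = 50, field_um = 250,
                      plane_depths_um = c(0, 40))
  cells <- place_cells(cfg, seed = 4)
  expect_equal(nrow(cells), 100)
  for (p in c(0, 40)) {
    cc <- cells[cells$depth_um == p, ]
    dmat <- as.matrix(dist(cbind(cc$x_um, cc$y_um)))
    expect_gte(min(dmat[upper.tri(dmat)]), 8)
  }
  expect_true(all(cells$pref_orientation_deg >= 0 &
                    cells$pref_orientation_deg < 180))
  expect_true(all(cells$pref_sf_cpd > 0 & cells$pref_sf_cpd <= 0.15))
})

test_that("column decorrelation spans columnar to independent planes", {
  near_vertical_dori <- function(decorr, seed) {
    cfg <- sheet_config(n_cells = 80, field_um = 250, map_length_um = 40,
                        plane_depths_um = c(0, 40),
                        column_decorrelation = decorr)
    cells <- place_cells(cfg, seed = seed)
    a <- cells[cells$depth_um == 0, ]
    b <- cells[cells$depth_um == 40, ]
    # preference difference between vertically adjacent cells
    d <- vapply(seq_len(nrow(a)), function(i) {
      j <- which.min((b$x_um - a$x_um[i])^2 + (b$y_um - a$y_um[i])^2)
      orientation_difference(a$pref_orientation_deg[i],
                             b$pref_orientation_deg[j])
    }, 0)
    mean(d)
  }
  columnar <- mean(vapply(1:3, function(s) near_vertical_dori(0, s), 0))
  independent <- mean(vapply(1:3, function(s) near_vertical_dori(1, s), 0))
  expect_lt(columnar, 25)        # shared map: vertical neighbours agree
  expect_gt(independent, 35)     # private maps: near-chance (45)
  expect_gt(independent - columnar, 10)
})

test_that("ground-truth kernels peak at the preference and share the bias", {
  grid <- build_design(toy_sequence(sf_max_cpd = 0.15))$grid
  w <- ground_truth_kernel(45, 0.05, grid, low_sf_bias_weight = 0)
  pk <- kernel_peak(w, grid)
  expect_equal(orientation_difference(pk$pref_orientation_deg, 45),
               0, tolerance = 6)
  expect_equal(log2(pk$pref_sf_cpd / 0.05), 0, tolerance = 0.3)
  expect_equal(max(w), 1)

  # identical preferences -> perfect similarity
  w2 <- ground_truth_kernel(45, 0.05, grid, low_sf_bias_weight = 0)
  expect_equal(tuning_similarity(w, w2), 1)

  # orthogonal preferences but a shared low-SF component -> correlated
  wa <- ground_truth_kernel(0, 0.08, grid, low_sf_bias_weight = 1)
  wb <- ground_truth_kernel(90, 0.08, grid, low_sf_bias_weight = 1)
  expect_gt(tuning_similarity(wa, wb), 0)
  wa0 <- ground_truth_kernel(0, 0.08, grid, low_sf_bias_weight = 0)
  wb0 <- ground_truth_kernel(90, 0.08, grid, low_sf_bias_weight = 0)
  expect_lt(tuning_similarity(wa0, wb0), tuning_similarity(wa, wb))
  expect_error(ground_truth_kernel(0, 0.5, grid), "outside")
})

test_that("zero-gain cells fire as constant-rate Poisson processes", {
  design <- build_design(toy_sequence(duration_s = 600))
  cells <- tibble::tibble(cell_id = 1:3, gain = 0, baseline_rate_hz = 2,
                          is_interneuron = FALSE)
  w <- matrix(1, nrow(design$grid), 3)
  spk <- simulate_spikes(cells, w, design, seed = 5)
  lam <- 2 / 15.5
  for (j in 1:3) {
    m <- mean(spk[, j])
    expect_equal(m, lam, tolerance = 0.1)
    expect_equal(var(spk[, j]) / m, 1, tolerance = 0.1)   # Poisson
  }
})

test_that("stimulus-locked rate modulation is linear in gain", {
  design <- build_design(toy_sequence(duration_s = 900, sf_max_cpd = 0.05,
                                      seed = 6))
  grid <- design$grid
  w <- matrix(ground_truth_kernel(90, 0.03, grid, low_sf_bias_weight = 0))
  mk_cells <- function(g) tibble::tibble(cell_id = 1, gain = g,
                                         baseline_rate_hz = 0.5,
                                         is_interneuron = FALSE)
  trig_mean <- function(spk) {
    lag2 <- saltpepper:::lagged_cond(design$frame_cond, 2L)
    as.numeric(tapply(spk[lag2 > 0], lag2[lag2 > 0], mean))
  }
  s1 <- trig_mean(simulate_spikes(mk_cells(2), w, design, seed = 7)[, 1])
  s2 <- trig_mean(simulate_spikes(mk_cells(4), w, design, seed = 7)[, 1])
  base <- 0.5 / 15.5
  fit <- lm.fit(cbind(s1 - base), s2 - base)
  expect_equal(unname(fit$coefficients), 2, tolerance = 0.2)
})

test_that("condition-triggered rates mirror the ground-truth kernel", {
  cfg <- sheet_config(n_cells = 6, duration_s = 1200, interneuron_frac = 0)
  ds <- simulate_dataset(cfg, seed = 8)
  lag2 <- saltpepper:::lagged_cond(ds$design$frame_cond, 2L)
  keep <- lag2 > 0
  for (j in 1:6) {
    trig <- tapply(ds$spikes[keep, j], lag2[keep], mean)
    trig_full <- numeric(nrow(ds$design$grid))
    trig_full[as.integer(names(trig))] <- trig
    expect_gt(cor(trig_full, ds$w_true[, j]), 0.6)
  }
})

test_that("calcium dynamics follow the AR(1) half-decay law", {
  gam <- ar1_decay(135, 15.5)
  frames_to_half <- 135 / (1000 / 15.5)
  expect_equal(frames_to_half, 2.0925)
  expect_equal(gam^frames_to_half, 0.5, tolerance = 1e-12)

  spk <- matrix(0, 60, 1); spk[11, 1] <- 1
  fl <- spikes_to_fluorescence(spk, 15.5, 135, noise_sigma = 0,
                               drift_amp = 0, neuropil_weight = 0, seed = 1)
  tr <- fl$raw[, 1]
  expect_equal(tr[1:10], rep(0, 10))
  expect_equal(tr[11:60], gam^(0:49), tolerance = 1e-12)
})

test_that("fluorescence synthesis is seeded and contaminated as configured", {
  set.seed(9)
  spk <- matrix(rpois(300 * 4, 0.05), 300, 4)
  f1 <- spikes_to_fluorescence(spk, seed = 3)
  f2 <- spikes_to_fluorescence(spk, seed = 3)
  expect_identical(f1, f2)
  # neuropil contamination induces shared variance in the raw traces
  f_clean <- spikes_to_fluorescence(spk, neuropil_weight = 0, seed = 3)
  shared <- function(m) mean(cor(m)[upper.tri(diag(4))])
  expect_gt(shared(f1$raw), shared(f_clean$raw))
})

test_that("interneuron-like traces pool neighbours and lose kurtosis", {
  cfg <- sheet_config(n_cells = 30, duration_s = 600,
                      interneuron_frac = 0.25)
  ds <- simulate_dataset(cfg, seed = 10)
  ts <- preprocess_traces(ds$raw, ds$neuropil)
  int <- ds$cells$is_interneuron
  expect_gt(sum(int), 2)
  expect_gte(mean(ts$kurtosis[int] < 7), 0.9)
  expect_gte(mean(ts$kurtosis[!int] > 15), 0.9)

  # with k = 1 and no tonic rate, an interneuron echoes its neighbour
  pyr <- ds$cells[!int, ]
  ints <- ds$cells[int, ]
  spk_int <- simulate_interneurons(ds$cells, ds$spikes[, !int, drop = FALSE],
                                   k_neighbours = 1, tonic_hz = 0, seed = 11)
  gam <- ar1_decay(135, 15.5)
  for (i in seq_len(min(3, nrow(ints)))) {
    d2 <- (pyr$x_um - ints$x_um[i])^2 + (pyr$y_um - ints$y_um[i])^2 +
      (pyr$depth_um - ints$depth_um[i])^2
    nb <- which.min(d2)
    ca_nb <- as.numeric(stats::filter(ds$spikes[, which(!int)[nb]], gam,
                                      method = "recursive"))
    ca_int <- as.numeric(stats::filter(spk_int[, i], gam,
                                       method = "recursive"))
    if (sd(ca_int) > 0 && sd(ca_nb) > 0) {
      expect_gt(cor(ca_int, ca_nb), 0.5)
    }
  }
  few <- ds$cells[c(which(!int)[1:3], which(int)), ]
  expect_error(simulate_interneurons(few, ds$spikes[, which(!int)[1:3]],
                                     k_neighbours = 10), "fewer pyramidal")
})

test_that("datasets are bitwise reproducible under a fixed seed", {
  cfg <- sheet_config(n_cells = 8, duration_s = 60)
  d1 <- simulate_dataset(cfg, seed = 12)
  d2 <- simulate_dataset(cfg, seed = 12)
  expect_identical(d1$raw, d2$raw)
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(d1$cells, d2$cells)
  d3 <- simulate_dataset(cfg, seed = 13)
  expect_false(identical(d1$raw, d3$raw))
})
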