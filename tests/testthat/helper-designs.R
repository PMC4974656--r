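# Small stimulus designs used across tests.  A reduced spatial-frequency
# cap shrinks the Hartley grid so ALS problems stay tiny.

toy_sequence <- function(duration_s = 60, sf_max_cpd = 0.03, seed = 1,
                         update_rate_hz = 4) {
  generate_sequence(duration_s, update_rate_hz, sf_max_cpd, seed = seed)
}

# a deterministic balanced sequence showing every grid condition once per
# block, aligned one condition per imaging frame
balanced_sequence <- function(n_blocks = 3, sf_max_cpd = 0.03, seed = 5) {
  grid <- hartley_grid(sf_max_cpd = sf_max_cpd)
  set.seed(seed)
  order <- as.vector(replicate(n_blocks, sample.int(nrow(grid))))
  conditions <- grid[order, ]
  conditions$onset_s <- seq_along(order) - 1
  structure(
    list(
      conditions = conditions[c("onset_s", "cond_id", "kx", "ky",
                                "orientation_deg", "sf_cpd", "fold_id")],
      grid = grid, update_rate_hz = 1, sf_max_cpd = sf_max_cpd,
      screen = screen_geometry(), duration_s = length(order), seed = seed
    ),
    class = "stimulus_sequence"
  )
}

# deterministic synthetic cell on a design: pure separable drive, no noise
noiseless_response <- function(design, pref_ori = 45, pref_sf = 0.05,
                               gain = 1, b = 0.2, a = 0.1,
                               running = NULL) {
  w <- ground_truth_kernel(pref_ori, pref_sf, design$grid,
                           low_sf_bias_weight = 0)
  v <- default_temporal_kernel(design$n_lags)
  if (is.null(running)) running <- rep(0, length(design$frame_cond))
  drive <- saltpepper:::lagged_drive(matrix(w), design, v)[, 1]
  list(y = gain * drive + b + a * running, w = w, v = v, running = running)
}
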