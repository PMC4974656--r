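#' Configuration of a synthetic cortical sheet
#'
#' Collects every knob of the synthetic-data generator.  Defaults describe
#' the study conditions the pipeline is designed for: a 20 min Hartley
#' session at 4 updates per second imaged at 15.5 Hz, about 50 cells in a
#' 250 um field per plane, GCaMP-like transients with a 135 ms half-decay,
#' and a preference map whose clustering is set by `map_length_um`.
#'
#' `map_length_um` is the standard deviation of the Gaussian kernel that
#' smooths the underlying preference field.  The default of 30 um was
#' calibrated once so that the pooled tuning-similarity curve of replicate
#' default sheets decays with an exponential-fit length constant of 40 um
#' (the similarity length scale the pipeline is designed to resolve); the
#' map autocorrelation itself is Gaussian, so no closed form links the
#' smoothing scale to the fitted exponential constant.  `map_length_um = 0`
#' gives a salt-and-pepper sheet with spatially independent preferences.
#'
#' @param n_cells Cells per imaging plane.
#' @param field_um Side of the square imaging field, um.
#' @param plane_depths_um Depths of the imaging planes, um (planes are
#'   typically 40 um apart).
#' @param map_length_um Gaussian s.d. of the preference-map smoothing, um;
#'   0 means salt-and-pepper.
#' @param column_decorrelation Fraction of cells per plane whose preference
#'   is drawn from an independent per-plane map instead of the shared
#'   (columnar) map; 0 = perfect columns, 1 = independent planes.
#' @param sf_log_mean,sf_log_sd Mean and s.d. of preferred spatial
#'   frequency on the log2 scale (cpd).
#' @param low_sf_bias_weight Weight of the low-spatial-frequency response
#'   component shared by all cells; produces the nonzero similarity
#'   asymptote seen at large cortical distances.
#' @param interneuron_frac Fraction of cells simulated as interneuron-like
#'   (pooled, tonic, low-kurtosis traces).
#' @param ori_bw_deg,sf_bw_oct Tuning bandwidths (orientation s.d. in
#'   degrees; spatial frequency s.d. in octaves).
#' @param gain_mean,gain_sdlog Log-normal stimulus gain across cells (Hz at
#'   the kernel peak); the spread leaves some cells below the model
#'   selection threshold, as in real populations.
#' @param baseline_rate_hz Tonic rate component of pyramidal cells, Hz.
#'   During simulation each cell's rest offset becomes
#'   `baseline_rate_hz - gain * theta`, where `theta` is the
#'   `1 - suprathreshold_frac` quantile of that cell's own linear drive:
#'   under the rectified-linear response the cell fires only when its
#'   drive exceeds its threshold, emulating the sparse, stimulus-locked
#'   firing of pyramidal cells.
#' @param suprathreshold_frac Fraction of frames on which a pyramidal
#'   cell's drive exceeds its firing threshold.
#' @param run_gain Additive rate offset while the animal runs, Hz.
#' @param duration_s,update_rate_hz,sf_max_cpd Stimulus parameters passed
#'   to [generate_sequence()].
#' @param imaging_rate_hz Imaging frame rate.
#' @param tau_half_ms Calcium indicator half-decay time, ms.
#' @param noise_sigma Gaussian measurement noise s.d. (fluorescence units;
#'   one inferred spike has unit amplitude).
#' @param drift_amp Amplitude of the slow baseline drift.
#' @param neuropil_weight Contamination weight of the shared neuropil
#'   signal in the raw ROI trace.
#' @param grid_step_um Sampling step of the preference maps.
#' @param min_sep_um Minimum distance between cell centres (soma
#'   exclusion).
#' @param roi_area_meanlog,roi_area_sdlog Log-normal ROI areas, um^2.
#' @param p_run Long-run fraction of frames spent running.
#' @param int_tonic_hz Tonic rate added to interneuron-like cells.
#' @param int_k_neighbours Number of nearest pyramidal cells an
#'   interneuron pools.
#' @param int_pool_gain Gain on the pooled pyramidal rate (interneurons
#'   fire far above pyramidal rates).
#' @param screen A [screen_geometry()].
#'
#' @return A list of class `sheet_config`.
#' @export
sheet_config <- function(n_cells = 50,
                         field_um = 250,
                         plane_depths_um = 0,
                         map_length_um = 30,
                         column_decorrelation = 0,
                         sf_log_mean = log2(0.04),
                         sf_log_sd = 0.5,
                         low_sf_bias_weight = 0.3,
                         interneuron_frac = 0.1,
                         ori_bw_deg = 20,
                         sf_bw_oct = 0.7,
                         gain_mean = 5,
                         gain_sdlog = 0.5,
                         baseline_rate_hz = 0.05,
                         suprathreshold_frac = 0.08,
                         run_gain = 0.3,
                         duration_s = 1200,
                         update_rate_hz = 4,
                         sf_max_cpd = 0.15,
                         imaging_rate_hz = 15.5,
                         tau_half_ms = 135,
                         noise_sigma = 0.08,
                         drift_amp = 0.1,
                         neuropil_weight = 0.7,
                         grid_step_um = 5,
                         min_sep_um = 8,
                         roi_area_meanlog = log(110),
                         roi_area_sdlog = 0.35,
                         p_run = 0.3,
                         int_tonic_hz = 3,
                         int_k_neighbours = 10,
                         int_pool_gain = 5,
                         screen = screen_geometry()) {
  cfg <- as.list(environment())
  if (cfg$n_cells < 2) abort("n_cells must be >= 2")
  if (cfg$map_length_um < 0) abort("map_length_um must be >= 0")
  if (cfg$column_decorrelation < 0 || cfg$column_decorrelation > 1) {
    abort("column_decorrelation must be in [0, 1]")
  }
  structure(cfg, class = "sheet_config")
}

# ---- preference maps -------------------------------------------------------

# dense band matrix applying a 1-D convolution that maps n + 2*pad points
# onto n (valid part only)
conv_band <- function(n, kern) {
  half <- (length(kern) - 1L) / 2L
  n_in <- n + 2L * half
  K <- matrix(0, n, n_in)
  for (j in seq_along(kern)) {
    K[cbind(seq_len(n), seq_len(n) + j - 1L)] <- kern[j]
  }
  K
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# smooth a (possibly complex) matrix sampled with margin `half` on each side
smooth_field <- function(z, sigma_cells) {
  if (sigma_cells <= 0) return(z)
  kern <- gaussian_kernel_1d(sigma_cells)
  half <- (length(kern) - 1L) / 2L
  n_out_r <- nrow(z) - 2L * half
  n_out_c <- ncol(z) - 2L * half
  Kr <- conv_band(n_out_r, kern)
  Kc <- conv_band(n_out_c, kern)
  Kr %*% z %*% t(Kc)
}

#' Generate smoothed orientation and spatial-frequency preference maps
#'
#' Complex white noise is smoothed with an isotropic Gaussian of s.d.
#' `map_length_um`; the orientation map is half the argument of the
#' smoothed field (so orientation lives on its natural 180-degree circle),
#' and the log spatial-frequency map is an independently smoothed real
#' field rescaled to the requested mean and s.d.  `map_length_um = 0`
#' returns spatially independent (salt-and-pepper) fields.
#'
#' @param field_um Side of the square field, um.
#' @param map_length_um Gaussian smoothing s.d., um.
#' @param grid_step_um Map sampling step, um.
#' @param sf_log_mean,sf_log_sd Target mean/s.d. of the log2 preferred
#'   spatial frequency.
#' @param seed RNG seed.
#'
#' @return A list of class `preference_maps` with node coordinates and the
#'   `orientation_deg` and `log2_sf` matrices.
#' @export
generate_preference_maps <- function(field_um, map_length_um,
                                     grid_step_um = 5,
                                     sf_log_mean = log2(0.04),
                                     sf_log_sd = 0.5,
                                     seed = 1) {
  if (grid_step_um <= 0) abort("grid_step_um must be > 0")
  set.seed(seed)
  n <- ceiling(field_um / grid_step_um) + 1L
  sigma_cells <- map_length_um / grid_step_um
  half <- if (sigma_cells > 0) max(1L, ceiling(4 * sigma_cells)) else 0L
  n_in <- n + 2L * half
  z <- matrix(complex(real = rnorm(n_in^2), imaginary = rnorm(n_in^2)), n_in)
  f <- matrix(rnorm(n_in^2), n_in)
  zs <- smooth_field(z, sigma_cells)   # returns the valid n x n interior
  fs <- smooth_field(f, sigma_cells)
  ori <- (Arg(zs) * 90 / pi) %% 180
  fsn <- (fs - mean(fs)) / sd(fs)
  structure(
    list(
      coord_um = (seq_len(n) - 1L) * grid_step_um,
      orientation_deg = ori,
      log2_sf = fsn * sf_log_sd + sf_log_mean,
      grid_step_um = grid_step_um,
      map_length_um = map_length_um,
      seed = seed
    ),
    class = "preference_maps"
  )
}

# nearest-node lookup of (orientation, log2 sf) preferences
sample_preferences <- function(maps, x_um, y_um) {
  i <- pmin(pmax(round(x_um / maps$grid_step_um) + 1L, 1L), nrow(maps$orientation_deg))
  j <- pmin(pmax(round(y_um / maps$grid_step_um) + 1L, 1L), ncol(maps$orientation_deg))
  idx <- cbind(i, j)
  tibble(
    pref_orientation_deg = maps$orientation_deg[idx],
    pref_sf_cpd = 2^maps$log2_sf[idx]
  )
}

# ---- cell placement --------------------------------------------------------

#' Place cells on the cortical sheet
#'
#' Draws uniform cell positions per plane with a minimum pairwise
#' separation (soma exclusion), log-normal ROI areas, and preferences
#' sampled from the sheet's preference maps.  With
#' `column_decorrelation > 0`, each cell's preference is replaced, with
#' that probability, by a draw from an independent per-plane map, so the
#' columnar (depth-invariant) structure degrades gracefully from perfect
#' columns (0) to independent planes (1).
#'
#' @param config A [sheet_config()].
#' @param seed RNG seed; defaults to the config's reproducible derivation.
#'
#' @return A tibble of cells: `cell_id`, `x_um`, `y_um`, `depth_um`,
#'   `roi_area_um2`, `pref_orientation_deg`, `pref_sf_cpd`, `gain`,
#'   `baseline_rate_hz`, `is_interneuron`.
#' @export
place_cells <- function(config, seed = 1) {
  stopifnot(inherits(config, "sheet_config"))
  shared <- generate_preference_maps(
    config$field_um, config$map_length_um, config$grid_step_um,
    config$sf_log_mean, config$sf_log_sd, seed = seed
  )
  planes <- config$plane_depths_um
  out <- vector("list", length(planes))
  sf_lim <- sf_range_limits(config)
  for (p in seq_along(planes)) {
    set.seed(seed + 1000L * p)
    pos <- draw_positions(config$n_cells, config$field_um, config$min_sep_um)
    private <- generate_preference_maps(
      config$field_um, config$map_length_um, config$grid_step_um,
      config$sf_log_mean, config$sf_log_sd, seed = seed + 7777L * p
    )
    set.seed(seed + 1000L * p + 1L)
    use_private <- runif(config$n_cells) < config$column_decorrelation
    pref <- sample_preferences(shared, pos$x, pos$y)
    pref_p <- sample_preferences(private, pos$x, pos$y)
    pref[use_private, ] <- pref_p[use_private, ]
    out[[p]] <- tibble(
      x_um = pos$x, y_um = pos$y, depth_um = planes[p],
      roi_area_um2 = rlnorm(config$n_cells, config$roi_area_meanlog,
                            config$roi_area_sdlog),
      pref_orientation_deg = pref$pref_orientation_deg,
      pref_sf_cpd = pmin(pmax(pref$pref_sf_cpd, sf_lim[1]), sf_lim[2]),
      gain = rlnorm(config$n_cells, log(config$gain_mean), config$gain_sdlog),
      is_interneuron = runif(config$n_cells) < config$interneuron_frac
    )

  }
  cells <- bind_rows(out)
  cells$cell_id <- seq_len(nrow(cells))
  cells[c("cell_id", setdiff(names(cells), "cell_id"))]
}

# clamp preferred SF into the representable part of the Fourier grid
sf_range_limits <- function(config) {
  grid <- hartley_grid(config$screen, config$sf_max_cpd)
  c(min(grid$sf_cpd), max(grid$sf_cpd))
}

draw_positions <- function(n, field_um, min_sep_um, max_tries = 200L) {
  x <- numeric(n); y <- numeric(n)
  placed <- 0L
  for (i in seq_len(n * max_tries)) {
    cx <- runif(1, 0, field_um); cy <- runif(1, 0, field_um)
    if (placed == 0L ||
        min((x[seq_len(placed)] - cx)^2 + (y[seq_len(placed)] - cy)^2) >=
          min_sep_um^2) {
      placed <- placed + 1L
      x[placed] <- cx; y[placed] <- cy
      if (placed == n) return(list(x = x, y = y))
    }
  }
  abort("could not place cells at the requested density")
}

# ---- ground-truth kernels --------------------------------------------------

#' Ground-truth Fourier-plane kernel of a synthetic cell
#'
#' A Gaussian bump in (orientation, log spatial frequency) coordinates of
#' the phase-pooled Fourier grid, plus `low_sf_bias_weight` times a fixed
#' low-spatial-frequency template shared by all cells.  The shared
#' component emulates the population-wide bias towards low spatial
#' frequencies that makes tuning similarity asymptote above zero at large
#' distances.  The kernel is normalized to unit peak.
#'
#' @param pref_ori Preferred orientation, degrees in `[0, 180)`.
#' @param pref_sf Preferred spatial frequency, cpd; must lie within the
#'   grid's frequency range.
#' @param grid Folded grid tibble (e.g. `design$grid`).
#' @param ori_bw_deg,sf_bw_oct Bandwidths (s.d.) in degrees / octaves.
#' @param low_sf_bias_weight Weight of the shared low-SF template.
#'
#' @return Numeric vector over the grid cells, peak value 1.
#' @export
ground_truth_kernel <- function(pref_ori, pref_sf, grid,
                                ori_bw_deg = 20, sf_bw_oct = 0.7,
                                low_sf_bias_weight = 0.3) {
  if (ori_bw_deg <= 0 || sf_bw_oct <= 0) abort("bandwidths must be > 0")
  if (pref_sf < min(grid$sf_cpd) || pref_sf > max(grid$sf_cpd)) {
    abort("pref_sf lies outside the grid's spatial-frequency range")
  }
  dori <- orientation_difference(grid$orientation_deg, pref_ori)
  dsf <- log2(grid$sf_cpd / pref_sf)
  bump <- exp(-dori^2 / (2 * ori_bw_deg^2) - dsf^2 / (2 * sf_bw_oct^2))
  template <- exp(-(grid$sf_cpd / 0.07)^2)
  w <- bump + low_sf_bias_weight * template
  w / max(w)
}

#' Default temporal kernel of the synthetic response
#'
#' A gamma-shaped lag profile, zero at lag 0, peaking near `peak_lag`
#' frames, normalized to unit Euclidean norm (the same constraint the
#' fitting stage imposes).
#'
#' @param n_lags Number of lags.
#' @param peak_lag Lag (frames) of the peak.
#' @return Numeric vector of length `n_lags` with unit norm.
#' @export
default_temporal_kernel <- function(n_lags = 8, peak_lag = 2) {
  tau <- seq_len(n_lags) - 1
  v <- (tau / peak_lag) * exp(1 - tau / peak_lag)
  v / sqrt(sum(v^2))
}

# ---- spiking and fluorescence ---------------------------------------------

#' Simulate Poisson spike counts from the linear response model
#'
#' Each cell fires as a linear-nonlinear-Poisson unit: the rate is the
#' rectified separable drive
#' `max(0, gain * sum_tau v(tau) * w(cond(t - tau)) + baseline + run_gain * r(t))`
#' and counts are Poisson with mean `rate / imaging_rate` per frame.  The
#' rectified-linear (rather than exponential) nonlinearity keeps the
#' estimand of the downstream linear regression equal to the ground-truth
#' kernel up to scale.
#'
#' @param cells Cell tibble from [place_cells()].
#' @param w_true Matrix of ground-truth kernels, grid cells x cells.
#' @param design A `stimulus_design`.
#' @param temporal_kernel Unit-norm lag profile, length `design$n_lags`.
#' @param running 0/1 running indicator per imaging frame.
#' @param run_gain Rate offset while running, Hz.
#' @param seed RNG seed.
#'
#' @return Integer matrix of spike counts, frames x cells.
#' @export
simulate_spikes <- function(cells, w_true, design,
                            temporal_kernel = default_temporal_kernel(design$n_lags),
                            running = NULL, run_gain = 0, seed = 1) {
  stopifnot(inherits(design, "stimulus_design"))
  T_ <- length(design$frame_cond)
  if (is.null(running)) running <- numeric(T_)
  drive <- lagged_drive(w_true, design, temporal_kernel)
  rate <- sweep(drive, 2, cells$gain, "*")
  rate <- sweep(rate, 2, cells$baseline_rate_hz, "+")
  rate <- rate + run_gain * running
  rate <- pmax(rate, 0)
  if (all(rate == 0)) warn("all simulated rates are zero")
  set.seed(seed)
  counts <- matrix(rpois(length(rate), rate / design$imaging_rate_hz),
                   nrow = T_)
  colnames(counts) <- cells$cell_id
  counts
}

# frames x cells matrix of sum_tau v(tau) * w[cond(t - tau)]
lagged_drive <- function(w, design, v) {
  w <- as.matrix(w)
  T_ <- length(design$frame_cond)
  out <- matrix(0, T_, ncol(w))
  w0 <- rbind(0, w)                       # row 1 = "no stimulus"
  for (tau in seq_along(v)) {
    idx <- lagged_cond(design$frame_cond, tau - 1L) + 1L
    out <- out + v[tau] * w0[idx, , drop = FALSE]
  }
  out
}

#' Simulate a running-state indicator
#'
#' Two-state Markov chain on the imaging clock with mean bout length
#' `mean_bout_s` and stationary running probability `p_run`.
#'
#' @param n_frames Number of frames.
#' @param imaging_rate_hz Frame rate.
#' @param p_run Stationary probability of running.
#' @param mean_bout_s Mean running-bout duration, s.
#' @param seed RNG seed.
#' @return Numeric 0/1 vector of length `n_frames`.
#' @export
simulate_running <- function(n_frames, imaging_rate_hz = 15.5, p_run = 0.3,
                             mean_bout_s = 10, seed = 1) {
  set.seed(seed)
  q_stop <- 1 / (mean_bout_s * imaging_rate_hz)       # leave running
  q_start <- q_stop * p_run / (1 - p_run)             # leave rest
  state <- numeric(n_frames)
  state[1] <- as.numeric(runif(1) < p_run)
  u <- runif(n_frames)
  for (t in 2:n_frames) {
    state[t] <- if (state[t - 1] == 1) as.numeric(u[t] > q_stop)
                else as.numeric(u[t] < q_start)
  }
  state
}

#' Convert spike counts to raw and neuropil fluorescence traces
#'
#' Calcium follows the AR(1) model `c(t) = gamma * c(t-1) + s(t)` with
#' `gamma = 2^(-dt_ms / tau_half_ms)`.  The shared neuropil trace is a
#' slow random process plus the mean population calcium; each raw ROI
#' trace is its own calcium plus `neuropil_weight` times the shared
#' neuropil, a slow sinusoidal drift, and i.i.d. Gaussian noise.  The
#' measured neuropil channel is the shared trace plus a small independent
#' noise.
#'
#' @param spikes Integer matrix, frames x cells.
#' @param imaging_rate_hz Frame rate.
#' @param tau_half_ms Indicator half-decay time, ms.
#' @param noise_sigma Measurement noise s.d.
#' @param drift_amp Amplitude of the slow baseline drift.
#' @param neuropil_weight Contamination weight.
#' @param seed RNG seed.
#'
#' @return List with matrices `raw`, `neuropil` (frames x cells) and the
#'   noiseless `calcium`.
#' @export
spikes_to_fluorescence <- function(spikes, imaging_rate_hz = 15.5,
                                   tau_half_ms = 135, noise_sigma = 0.15,
                                   drift_amp = 0.2, neuropil_weight = 0.7,
                                   seed = 1) {
  if (tau_half_ms <= 0) abort("tau_half_ms must be > 0")
  spikes <- as.matrix(spikes)
  T_ <- nrow(spikes); n <- ncol(spikes)
  gam <- ar1_decay(tau_half_ms, imaging_rate_hz)
  calcium <- apply(spikes, 2, function(s) {
    as.numeric(stats::filter(s, gam, method = "recursive"))
  })
  calcium <- matrix(calcium, T_, n)
  set.seed(seed)
  slow <- as.numeric(stats::filter(rnorm(T_), 0.995, method = "recursive"))
  slow <- 0.2 * slow / max(sd(slow), 1e-12)
  shared_np <- slow + rowMeans(calcium)
  t_s <- seq_len(T_) / imaging_rate_hz
  phase <- runif(n, 0, 2 * pi)
  drift <- drift_amp * sin(outer(2 * pi * t_s / (max(t_s) / 1.5), phase, "+"))
  raw <- calcium + neuropil_weight * shared_np + drift +
    matrix(rnorm(T_ * n, 0, noise_sigma), T_, n)
  neuropil <- shared_np + matrix(rnorm(T_ * n, 0, noise_sigma * 0.3), T_, n)
  list(raw = raw, neuropil = neuropil, calcium = calcium)
}

#' Per-frame AR(1) decay factor of the calcium indicator
#'
#' @param tau_half_ms Half-decay time, ms.
#' @param imaging_rate_hz Frame rate.
#' @return `gamma = 2^(-dt_ms / tau_half_ms)` in (0, 1).
#' @export
ar1_decay <- function(tau_half_ms, imaging_rate_hz) {
  2^(-(1000 / imaging_rate_hz) / tau_half_ms)
}

#' Simulate interneuron-like spike trains
#'
#' Interneurons pool the activity of nearby pyramidal cells: each
#' interneuron's rate is a temporally smoothed mean of the rates of its
#' `k_neighbours` nearest pyramidal cells plus a high tonic baseline,
#' which yields dense, low-kurtosis traces in contrast to the sparse
#' transients of pyramidal cells.
#'
#' @param cells Cell tibble (`is_interneuron` marks targets).
#' @param pyr_spikes Spike-count matrix of the pyramidal cells (frames x
#'   pyramidal cells, columns named by `cell_id`).
#' @param imaging_rate_hz Frame rate.
#' @param k_neighbours Number of pooled neighbours.
#' @param tonic_hz Tonic rate, Hz.
#' @param pool_gain Gain applied to the pooled pyramidal rate.
#' @param smooth_frames Width of the temporal boxcar applied to the pooled
#'   rate.
#' @param seed RNG seed.
#'
#' @return Integer matrix, frames x interneurons (columns named by
#'   `cell_id`).
#' @export
simulate_interneurons <- function(cells, pyr_spikes, imaging_rate_hz = 15.5,
                                  k_neighbours = 10, tonic_hz = 3,
                                  pool_gain = 5, smooth_frames = 8,
                                  seed = 1) {
  if (k_neighbours < 1) abort("k_neighbours must be >= 1")
  pyr <- cells[!cells$is_interneuron, ]
  ints <- cells[cells$is_interneuron, ]
  if (nrow(pyr) < k_neighbours) abort("fewer pyramidal cells than k_neighbours")
  if (nrow(ints) == 0) {
    return(matrix(integer(0), nrow(pyr_spikes), 0))
  }
  T_ <- nrow(pyr_spikes)
  box <- rep(1 / smooth_frames, smooth_frames)
  set.seed(seed)
  out <- matrix(0L, T_, nrow(ints))
  for (i in seq_len(nrow(ints))) {
    d2 <- (pyr$x_um - ints$x_um[i])^2 + (pyr$y_um - ints$y_um[i])^2 +
      (pyr$depth_um - ints$depth_um[i])^2
    nb <- order(d2)[seq_len(k_neighbours)]
    pooled <- rowMeans(pyr_spikes[, nb, drop = FALSE]) * imaging_rate_hz
    sm <- as.numeric(stats::filter(pooled, box, sides = 1))
    sm[is.na(sm)] <- pooled[is.na(sm)]
    rate <- pool_gain * sm + tonic_hz
    out[, i] <- rpois(T_, rate / imaging_rate_hz)
  }
  colnames(out) <- ints$cell_id
  out
}

# ---- full dataset ----------------------------------------------------------

#' Simulate a complete synthetic imaging session
#'
#' Runs the whole generative model: Hartley stimulus, preference maps,
#' cell placement, ground-truth kernels, Poisson spiking (pyramidal and
#' interneuron-like), and fluorescence synthesis.  All randomness derives
#' from `seed`; identical seeds give identical datasets.
#'
#' @param config A [sheet_config()].
#' @param seed Integer RNG seed.
#'
#' @return An object of class `synthetic_dataset`: cells tibble, matrices
#'   `w_true` (grid x cells), `spikes`, `raw`, `neuropil` (frames x
#'   cells), the `stimulus`, `design`, `running`, `v_true`, and the
#'   config.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(sheet_config(n_cells = 10, duration_s = 60), seed = 1)
#' dim(ds$raw)
#' }
#' @export
simulate_dataset <- function(config = sheet_config(), seed = 1) {
  stopifnot(inherits(config, "sheet_config"))
  stim <- generate_sequence(config$duration_s, config$update_rate_hz,
                            config$sf_max_cpd, config$screen,
                            seed = seed + 11L)
  design <- build_design(stim, config$imaging_rate_hz)
  cells <- place_cells(config, seed = seed + 23L)
  w_true <- vapply(seq_len(nrow(cells)), function(i) {
    ground_truth_kernel(cells$pref_orientation_deg[i], cells$pref_sf_cpd[i],
                        design$grid, config$ori_bw_deg, config$sf_bw_oct,
                        config$low_sf_bias_weight)
  }, numeric(nrow(design$grid)))
  colnames(w_true) <- cells$cell_id
  T_ <- length(design$frame_cond)
  running <- simulate_running(T_, config$imaging_rate_hz, config$p_run,
                              seed = seed + 31L)
  v_true <- default_temporal_kernel(design$n_lags)
  # firing threshold at a fixed quantile of each cell's own linear drive
  drive <- lagged_drive(w_true, design, v_true)
  theta <- apply(drive, 2, quantile, probs = 1 - config$suprathreshold_frac)
  cells$baseline_rate_hz <- config$baseline_rate_hz - cells$gain * theta
  spikes <- simulate_spikes(cells, w_true, design, v_true, running,
                            config$run_gain, seed = seed + 41L)
  if (any(cells$is_interneuron)) {
    pyr_cols <- which(!cells$is_interneuron)
    int_spk <- simulate_interneurons(
      cells, spikes[, pyr_cols, drop = FALSE], config$imaging_rate_hz,
      min(config$int_k_neighbours, length(pyr_cols)),
      config$int_tonic_hz, config$int_pool_gain, seed = seed + 43L
    )
    spikes[, cells$is_interneuron] <- int_spk
  }
  fl <- spikes_to_fluorescence(spikes, config$imaging_rate_hz,
                               config$tau_half_ms, config$noise_sigma,
                               config$drift_amp, config$neuropil_weight,
                               seed = seed + 53L)
  structure(
    list(
      cells = cells, w_true = w_true, v_true = v_true,
      stimulus = stim, design = design, running = running,
      spikes = spikes, raw = fl$raw, neuropil = fl$neuropil,
      imaging_rate_hz = config$imaging_rate_hz,
      config = config, seed = seed
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d cells (%d interneuron-like), %d frames at %g Hz, seed %d\n",
    nrow(x$cells), sum(x$cells$is_interneuron), nrow(x$raw),
    x$imaging_rate_hz, x$seed
  ))
  invisible(x)
}
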