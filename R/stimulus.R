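#' Screen geometry of the stimulus display
#'
#' Describes the physical display and viewing distance, and derives the
#' visual angles subtended by the screen.  Spatial frequencies in cycles
#' per degree are computed against these derived angles.
#'
#' @param width_cm,height_cm Physical screen size in cm.
#' @param distance_cm Viewing distance in cm.
#'
#' @return An object of class `screen_geometry`: a list with the physical
#'   dimensions plus `width_deg` and `height_deg`, the full horizontal and
#'   vertical visual angles in degrees.
#' @examples
#' scr <- screen_geometry()
#' floor(scr$width_deg)   # 112
#' floor(scr$height_deg)  # 80
#' @export
screen_geometry <- function(width_cm = 60, height_cm = 34, distance_cm = 20) {
  if (!is.numeric(width_cm) || width_cm <= 0 ||
      !is.numeric(height_cm) || height_cm <= 0) {
    abort("screen dimensions must be positive")
  }
  structure(
    list(
      width_cm = width_cm,
      height_cm = height_cm,
      distance_cm = distance_cm,
      width_deg = visual_angle(width_cm, distance_cm),
      height_deg = visual_angle(height_cm, distance_cm)
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %g x %g cm at %g cm (%d x %d deg)\n",
    x$width_cm, x$height_cm, x$distance_cm,
    trunc(x$width_deg), trunc(x$height_deg)
  ))
  invisible(x)
}

#' Visual angle subtended by a screen extent
#'
#' Converts a physical extent viewed at a given distance into the full
#' visual angle `2 * atan(extent / (2 * distance))`, in degrees.
#'
#' @param extent_cm Physical extent in cm (>= 0).
#' @param distance_cm Viewing distance in cm (> 0).
#' @param truncate If `TRUE`, truncate to whole degrees (the convention
#'   used when quoting screen coverage).
#'
#' @return Visual angle in degrees.
#' @examples
#' visual_angle(60, 20, truncate = TRUE)  # 112
#' visual_angle(34, 20, truncate = TRUE)  # 80
#' @export
visual_angle <- function(extent_cm, distance_cm, truncate = FALSE) {
  if (any(distance_cm <= 0)) abort("distance_cm must be > 0")
  if (any(extent_cm < 0)) abort("extent_cm must be >= 0")
  ang <- 2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
  if (truncate) trunc(ang) else ang
}

#' Hartley basis image
#'
#' Renders one Hartley basis function on an `n x n` pixel grid:
#' `H(x, y) = cas(2 * pi * (kx * x + ky * y) / n)` with
#' `cas(z) = cos(z) + sin(z)`.  Distinct `(kx, ky)` images are mutually
#' orthogonal on the discrete torus; each indexes one combination of
#' orientation, spatial frequency and spatial phase.
#'
#' @param kx,ky Integer Fourier indices, `|kx|, |ky| < n_pixels / 2`.
#' @param n_pixels Image side in pixels (>= 2).
#'
#' @return An `n_pixels x n_pixels` numeric matrix with values in
#'   `[-sqrt(2), sqrt(2)]`.
#' @examples
#' h <- hartley_image(1, 0, 16)
#' range(h)
#' @export
hartley_image <- function(kx, ky, n_pixels) {
  if (n_pixels < 2) abort("n_pixels must be >= 2")
  if (abs(kx) >= n_pixels / 2 || abs(ky) >= n_pixels / 2) {
    abort("|kx| and |ky| must be below the Nyquist index n_pixels / 2")
  }
  idx <- seq_len(n_pixels) - 1
  phase <- 2 * pi * outer(kx * idx, ky * idx, "+") / n_pixels
  cos(phase) + sin(phase)
}

#' Map Fourier indices to orientation and spatial frequency
#'
#' Converts integer Hartley indices `(kx, ky)` into grating orientation and
#' spatial frequency given the screen geometry.  Frequencies along x and y
#' are `kx / width_deg` and `ky / height_deg` cycles per degree.  Orientation
#' is that of the grating (perpendicular to the wave vector), reduced modulo
#' 180 degrees with 0 = horizontal grating.  `(kx, ky)` and `(-kx, -ky)`
#' map to the same point: they differ only in spatial phase.
#'
#' @param kx,ky Integer Fourier indices (vectorized).
#' @param screen A [screen_geometry()].
#'
#' @return A tibble with columns `kx`, `ky`, `orientation_deg`, `sf_cpd`
#'   and `is_dc`.  The DC condition has undefined orientation (`NA`).
#' @export
condition_to_fourier <- function(kx, ky, screen = screen_geometry()) {
  wx <- kx / screen$width_deg
  wy <- ky / screen$height_deg
  ori <- (atan2(wy, wx) * 180 / pi + 90) %% 180
  dc <- kx == 0 & ky == 0
  ori[dc] <- NA_real_
  tibble(
    kx = as.integer(kx), ky = as.integer(ky),
    orientation_deg = ori,
    sf_cpd = sqrt(wx^2 + wy^2),
    is_dc = dc
  )
}

#' Hartley condition grid below a spatial-frequency cap
#'
#' Enumerates all integer `(kx, ky)` whose spatial frequency does not
#' exceed `sf_max_cpd` on the given screen, excluding the DC term.  Each
#' condition carries a `fold_id` identifying its phase-pooled pair:
#' `(kx, ky)` and `(-kx, -ky)` share one `fold_id` because averaging over
#' spatial phase pools them into a single orientation/frequency cell.
#'
#' @param screen A [screen_geometry()].
#' @param sf_max_cpd Maximum spatial frequency in cycles per degree.
#'
#' @return A tibble of conditions: `cond_id`, `kx`, `ky`, `orientation_deg`,
#'   `sf_cpd`, `fold_id`.
#' @export
hartley_grid <- function(screen = screen_geometry(), sf_max_cpd = 0.15) {
  kx_max <- floor(sf_max_cpd * screen$width_deg)
  ky_max <- floor(sf_max_cpd * screen$height_deg)
  g <- expand.grid(kx = -kx_max:kx_max, ky = -ky_max:ky_max)
  info <- condition_to_fourier(g$kx, g$ky, screen)
  info <- info[!info$is_dc & info$sf_cpd <= sf_max_cpd, ]
  if (nrow(info) == 0) abort("no Hartley conditions below sf_max_cpd")
  # representative of the phase pair: kx > 0, or kx == 0 and ky > 0
  flip <- info$kx < 0 | (info$kx == 0 & info$ky < 0)
  rep_kx <- ifelse(flip, -info$kx, info$kx)
  rep_ky <- ifelse(flip, -info$ky, info$ky)
  key <- paste(rep_kx, rep_ky)
  info$fold_id <- as.integer(factor(key, levels = unique(key[!flip])))
  info$cond_id <- seq_len(nrow(info))
  as_tibble(info[c("cond_id", "kx", "ky", "orientation_deg", "sf_cpd", "fold_id")])
}

#' Generate a random Hartley stimulus sequence
#'
#' Draws conditions uniformly and independently from the Hartley grid at
#' the given update rate.  This reproduces the experimental protocol of a
#' flashed pseudo-random grating sequence: each update shows one basis
#' function with random orientation, spatial frequency and phase.
#'
#' @param duration_s Sequence duration in seconds (default 1200, a 20 min
#'   session).
#' @param update_rate_hz Stimulus updates per second (default 4).
#' @param sf_max_cpd Maximum spatial frequency (default 0.15 cpd).
#' @param screen A [screen_geometry()].
#' @param seed Integer RNG seed; identical seeds give identical sequences.
#'
#' @return An object of class `stimulus_sequence`: list with `conditions`
#'   (tibble `onset_s`, `cond_id`, `kx`, `ky`, `orientation_deg`, `sf_cpd`,
#'   `fold_id`), the grid, rates and seed.
#' @examples
#' seq <- generate_sequence(duration_s = 10, seed = 1)
#' nrow(seq$conditions)  # 40
#' @export
generate_sequence <- function(duration_s = 1200, update_rate_hz = 4,
                              sf_max_cpd = 0.15,
                              screen = screen_geometry(), seed = 1) {
  if (duration_s <= 0) abort("duration_s must be > 0")
  grid <- hartley_grid(screen, sf_max_cpd)
  n <- floor(duration_s * update_rate_hz)
  set.seed(seed)
  draw <- sample.int(nrow(grid), n, replace = TRUE)
  conditions <- grid[draw, ]
  conditions$onset_s <- (seq_len(n) - 1) / update_rate_hz
  structure(
    list(
      conditions = as_tibble(conditions[c(
        "onset_s", "cond_id", "kx", "ky", "orientation_deg", "sf_cpd", "fold_id"
      )]),
      grid = grid,
      update_rate_hz = update_rate_hz,
      sf_max_cpd = sf_max_cpd,
      screen = screen,
      duration_s = duration_s,
      seed = seed
    ),
    class = "stimulus_sequence"
  )
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf(
    "<stimulus_sequence> %d conditions at %g Hz (%.0f s), sf <= %g cpd, %d grid cells\n",
    nrow(x$conditions), x$update_rate_hz, x$duration_s, x$sf_max_cpd, nrow(x$grid)
  ))
  invisible(x)
}

#' Write / read a stimulus log
#'
#' The stimulus log is a plain CSV with columns `onset_s`, `kx`, `ky`,
#' `orientation_deg`, `sf_cpd`.
#'
#' @param seq A `stimulus_sequence`.
#' @param path File path.
#' @export
write_stimulus_log <- function(seq, path) {
  df <- seq$conditions[c("onset_s", "kx", "ky", "orientation_deg", "sf_cpd")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_log
#' @param screen A [screen_geometry()] used to rebuild grid annotations.
#' @param sf_max_cpd Spatial-frequency cap of the grid the log was drawn from.
#' @return `read_stimulus_log()` returns a `stimulus_sequence`.
#' @export
read_stimulus_log <- function(path, screen = screen_geometry(),
                              sf_max_cpd = 0.15) {
  df <- utils::read.csv(path)
  need <- c("onset_s", "kx", "ky")
  if (!all(need %in% names(df))) {
    abort(paste("stimulus log is missing columns:",
                paste(setdiff(need, names(df)), collapse = ", ")))
  }
  grid <- hartley_grid(screen, sf_max_cpd)
  idx <- match(paste(df$kx, df$ky), paste(grid$kx, grid$ky))
  if (anyNA(idx)) abort("stimulus log contains conditions outside the grid")
  onsets <- df$onset_s
  dt <- diff(onsets)
  if (length(dt) && any(dt <= 0)) abort("onsets must be strictly increasing")
  rate <- if (length(dt)) 1 / stats::median(dt) else 4
  conditions <- grid[idx, ]
  conditions$onset_s <- onsets
  structure(
    list(
      conditions = as_tibble(conditions[c(
        "onset_s", "cond_id", "kx", "ky", "orientation_deg", "sf_cpd", "fold_id"
      )]),
      grid = grid,
      update_rate_hz = rate,
      sf_max_cpd = sf_max_cpd,
      screen = screen,
      duration_s = max(onsets) + 1 / rate,
      seed = NA_integer_
    ),
    class = "stimulus_sequence"
  )
}

#' Realize the stimulus on the imaging clock
#'
#' Builds the design information needed by the kernel regression: for each
#' imaging frame, the condition on screen at that frame's mid-time
#' (nearest preceding onset).  With `fold_symmetry = TRUE` (the default)
#' `(kx, ky)` and `(-kx, -ky)` share one grid cell, which averages
#' responses across spatial phase so that simple and complex cells alike
#' yield a single orientation/frequency profile.
#'
#' @param seq A `stimulus_sequence`.
#' @param imaging_rate_hz Imaging frame rate (default 15.5).
#' @param n_lags Number of temporal lags of the response model (default 8,
#'   about half a second at 15.5 Hz).
#' @param fold_symmetry Pool phase pairs into one grid cell?
#' @param n_frames Number of imaging frames; defaults to covering the
#'   stimulus duration.
#'
#' @return An object of class `stimulus_design`: `frame_cond` (integer
#'   grid-cell index per frame, 0 before the first onset), `grid` (tibble
#'   of design grid cells), `n_lags`, `imaging_rate_hz`, `times_s`.
#' @export
build_design <- function(seq, imaging_rate_hz = 15.5, n_lags = 8,
                         fold_symmetry = TRUE, n_frames = NULL) {
  stopifnot(inherits(seq, "stimulus_sequence"), n_lags >= 1)
  onsets <- seq$conditions$onset_s
  if (any(diff(onsets) <= 0)) abort("overlapping or non-increasing onsets")
  if (is.null(n_frames)) n_frames <- ceiling(seq$duration_s * imaging_rate_hz)
  times <- (seq_len(n_frames) - 0.5) / imaging_rate_hz
  slot <- findInterval(times, onsets)         # 0 before first onset
  # a condition stays on screen until the next onset or one update period
  off <- c(onsets[-1], onsets[length(onsets)] + 1 / seq$update_rate_hz)
  on_screen <- slot >= 1 & times < off[pmax(slot, 1)]
  if (fold_symmetry) {
    cond <- seq$conditions$fold_id[pmax(slot, 1)]
    grid <- folded_grid(seq$grid)
  } else {
    cond <- seq$conditions$cond_id[pmax(slot, 1)]
    grid <- seq$grid
  }
  cond[!on_screen] <- 0L
  structure(
    list(
      frame_cond = as.integer(cond),
      grid = grid,
      full_grid = seq$grid,
      n_lags = as.integer(n_lags),
      fold_symmetry = fold_symmetry,
      imaging_rate_hz = imaging_rate_hz,
      times_s = times,
      screen = seq$screen
    ),
    class = "stimulus_design"
  )
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat(sprintf(
    "<stimulus_design> %d frames at %g Hz, %d grid cells (%s), %d lags\n",
    length(x$frame_cond), x$imaging_rate_hz, nrow(x$grid),
    if (x$fold_symmetry) "phase-pooled" else "full plane", x$n_lags
  ))
  invisible(x)
}

# one row per phase-pooled cell, keyed by fold_id and ordered by it
folded_grid <- function(grid) {
  reps <- grid[!duplicated(grid$fold_id), ]
  reps <- reps[order(reps$fold_id), ]
  as_tibble(reps[c("fold_id", "kx", "ky", "orientation_deg", "sf_cpd")])
}

#' Expand a phase-pooled kernel to the full Fourier plane
#'
#' Kernels are estimated on the folded (phase-pooled) grid.  For display
#' the kernel is symmetrized back to the full plane, where `(kx, ky)` and
#' `(-kx, -ky)` carry the same value and the origin sits in the middle.
#'
#' @param w Numeric vector over the folded grid cells of `design`.
#' @param design A `stimulus_design` with `fold_symmetry = TRUE`.
#'
#' @return A tibble `kx`, `ky`, `value` covering both half-planes.
#' @export
symmetrize_kernel <- function(w, design) {
  stopifnot(inherits(design, "stimulus_design"))
  g <- design$full_grid
  tibble(kx = g$kx, ky = g$ky, value = w[g$fold_id])
}

# per-frame condition index shifted by lag tau (frames), zero-padded
lagged_cond <- function(frame_cond, tau) {
  if (tau == 0) return(frame_cond)
  c(integer(tau), frame_cond[seq_len(length(frame_cond) - tau)])
}
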