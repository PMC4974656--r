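#' Robust neuropil correction of an ROI trace
#'
#' Removes the neuropil contribution from a raw ROI trace by projecting
#' out a robust linear prediction: `corrected = raw - (alpha + beta *
#' neuropil)`, where `(alpha, beta)` minimize the sum of absolute
#' residuals.  Least absolute deviations make the fit insensitive to the
#' sparse positive calcium transients riding on the contaminated trace;
#' `beta` is clipped to `[0, 2]` to prevent pathological over-subtraction.
#'
#' @param raw,neuropil Equal-length numeric vectors (length >= 100), or
#'   matrices with one column per ROI.
#'
#' @return For vectors, the corrected trace with attributes `alpha` and
#'   `beta`; for matrices, a corrected matrix (coefficients per column in
#'   attributes).
#' @export
neuropil_correct <- function(raw, neuropil) {
  if (is.matrix(raw)) {
    stopifnot(is.matrix(neuropil), all(dim(raw) == dim(neuropil)))
    out <- raw
    alpha <- beta <- numeric(ncol(raw))
    for (j in seq_len(ncol(raw))) {
      cj <- neuropil_correct(raw[, j], neuropil[, j])
      out[, j] <- cj
      alpha[j] <- attr(cj, "alpha"); beta[j] <- attr(cj, "beta")
    }
    attr(out, "alpha") <- alpha; attr(out, "beta") <- beta
    return(out)
  }
  if (length(raw) != length(neuropil)) abort("raw and neuropil lengths differ")
  if (length(raw) < 100) abort("traces must have length >= 100")
  if (sd(neuropil) == 0) {
    out <- raw
    attr(out, "alpha") <- 0; attr(out, "beta") <- 0
    return(out)
  }
  lad <- function(b) {
    r <- raw - b * neuropil
    sum(abs(r - median(r)))
  }
  beta <- optimize(lad, c(0, 2), tol = 1e-6)$minimum
  # convex objective: check the clip boundaries explicitly
  for (b in c(0, 2)) if (lad(b) < lad(beta)) beta <- b
  alpha <- median(raw - beta * neuropil)
  out <- raw - alpha - beta * neuropil
  attr(out, "alpha") <- alpha; attr(out, "beta") <- beta
  out
}

#' Noise level of a calcium trace
#'
#' Estimates the measurement noise standard deviation as the (Gaussian
#' consistent) median absolute deviation of the first-order derivative of
#' the trace divided by `sqrt(2)`.  Differencing removes the slow calcium
#' dynamics; the MAD is insensitive to the remaining transient onsets;
#' the `sqrt(2)` undoes the variance doubling of differencing.
#'
#' @param trace Numeric vector, length >= 3.
#' @return Estimated noise s.d. (same units as the trace).
#' @examples
#' estimate_noise(rnorm(1e4))  # ~1
#' @export
estimate_noise <- function(trace) {
  if (length(trace) < 3) abort("trace must have length >= 3")
  mad(diff(trace)) / sqrt(2)
}

#' Constrained non-negative deconvolution of a calcium trace
#'
#' Infers a non-negative spike signal from a neuropil-corrected
#' fluorescence trace under the AR(1) calcium model
#' `c(t) = gamma * c(t-1) + s(t)`.  Solves the constrained convex program
#'
#'   minimize  sum_t s(t)
#'   subject to  s >= 0  and  || trace - c - drift ||_2 <= sigma * sqrt(T)
#'
#' where the drift is an unconstrained natural cubic spline with
#' `n_knots` interior knots equally spaced in time (absorbing slow
#' baseline fluctuations).  The program is solved through its Lagrangian:
#' for a fixed penalty the l1-penalized problem is solved by a
#' pool-adjacent-violators pass alternated with the spline fit, and the
#' penalty is bisected until the residual norm meets the noise budget.
#' If even the unpenalized fit cannot reach the budget the program is
#' infeasible; the minimal-residual solution is returned with
#' `feasible = FALSE`.
#'
#' @param trace Corrected fluorescence, length `T >= 2 * n_knots`.
#' @param gamma Per-frame AR(1) decay factor in (0, 1); see [ar1_decay()].
#' @param sigma Noise s.d. (> 0), e.g. from [estimate_noise()].
#' @param n_knots Interior spline knots for the drifting baseline.
#' @param max_alt Maximum spline/spike alternations per penalty value
#'   (convergence is usually much earlier; alternations are warm-started
#'   across the penalty search).
#'
#' @return A list of class `deconvolution`: `spikes`, `calcium`, `drift`,
#'   `lambda` (the penalty solving the constrained program), `objective`
#'   (`sum(spikes)`), `residual_norm`, `sigma`, `feasible`.
#' @export
deconvolve <- function(trace, gamma, sigma, n_knots = 10, max_alt = 200) {
  T_ <- length(trace)
  if (sigma <= 0) abort("sigma must be > 0")
  if (gamma <= 0 || gamma >= 1) abort("gamma must be in (0, 1)")
  if (T_ < 2 * n_knots) abort("trace too short for the spline baseline")
  B <- drift_basis(T_, n_knots)
  qrB <- qr(B)
  target <- sigma^2 * T_

  # spline/spike block descent, warm-started across penalty values so the
  # outer bisection costs only a few passes per step
  drift_state <- qr.fitted(qrB, trace)
  solve_pen <- function(lambda) {
    drift <- drift_state
    c_hat <- numeric(T_)
    rss_old <- Inf; obj_old <- Inf
    for (it in seq_len(max_alt)) {
      c_hat <- oasis_ar1(trace - drift, gamma, lambda)
      drift <- qr.fitted(qrB, trace - c_hat)
      rss <- sum((trace - c_hat - drift)^2)
      obj <- c_hat[T_] + (1 - gamma) * sum(c_hat[-T_])   # = sum of spikes
      if (abs(rss_old - rss) <= 1e-12 * max(rss, 1) &&
          abs(obj_old - obj) <= 1e-8 * max(obj, 1)) break
      rss_old <- rss; obj_old <- obj
    }
    drift_state <<- drift
    list(calcium = c_hat, drift = drift,
         rss = sum((trace - c_hat - drift)^2))
  }

  fit0 <- solve_pen(0)
  if (fit0$rss > target * (1 + 1e-9)) {
    sol <- fit0; lambda <- 0; feasible <- FALSE
  } else {
    feasible <- TRUE
    lo <- 0; sol_lo <- fit0
    hi <- max(sd(trace), sigma)
    fit_hi <- solve_pen(hi)
    n_try <- 0
    while (fit_hi$rss <= target && n_try < 60) {
      lo <- hi; sol_lo <- fit_hi
      hi <- hi * 4
      fit_hi <- solve_pen(hi)
      n_try <- n_try + 1
    }
    if (fit_hi$rss <= target) {
      # even huge penalties stay within budget: the zero-spike solution fits
      sol_lo <- fit_hi; lo <- hi
    } else {
      for (i in seq_len(50)) {
        mid <- (lo + hi) / 2
        fit_mid <- solve_pen(mid)
        if (fit_mid$rss <= target) {
          lo <- mid; sol_lo <- fit_mid
          if (fit_mid$rss >= target * (1 - 1e-9)) break
        } else hi <- mid
      }
    }
    sol <- sol_lo; lambda <- lo
  }
  spikes <- sol$calcium - gamma * c(0, sol$calcium[-T_])
  spikes[spikes < 0] <- 0
  structure(
    list(
      spikes = spikes, calcium = sol$calcium, drift = as.numeric(sol$drift),
      lambda = lambda, objective = sum(spikes),
      residual_norm = sqrt(sol$rss), sigma = sigma, feasible = feasible
    ),
    class = "deconvolution"
  )
}

# intercept + natural cubic spline with n_knots interior knots
drift_basis <- function(T_, n_knots) {
  knots <- seq(1, T_, length.out = n_knots + 2)[-c(1, n_knots + 2)]
  cbind(1, splines::ns(seq_len(T_), knots = knots,
                       Boundary.knots = c(1, T_)))
}

#' @export
print.deconvolution <- function(x, ...) {
  cat(sprintf(
    "<deconvolution> %d frames, %d active spike frames, lambda %.4g, %s\n",
    length(x$spikes), sum(x$spikes > 1e-8), x$lambda,
    if (x$feasible) "feasible" else "INFEASIBLE (minimal-residual fallback)"
  ))
  invisible(x)
}

#' Non-excess sample kurtosis of a trace
#'
#' `m4 / m2^2`, the fourth central moment over the squared variance.  A
#' Gaussian signal scores 3; sparse transient-dominated calcium traces
#' score far higher, which is what separates putative excitatory cells
#' from the dense, tonic signals of interneurons.
#'
#' @param trace Numeric vector, length >= 4.
#' @return The kurtosis, or `NA` (with a warning) for a zero-variance
#'   trace.
#' @export
trace_kurtosis <- function(trace) {
  if (length(trace) < 4) abort("trace must have length >= 4")
  m <- mean(trace)
  m2 <- mean((trace - m)^2)
  if (m2 == 0) {
    warn("zero-variance trace: kurtosis undefined")
    return(NA_real_)
  }
  mean((trace - m)^4) / m2^2
}

#' Classify a cell as putative excitatory by trace kurtosis
#'
#' Cells whose corrected fluorescence kurtosis falls below the threshold
#' are flagged as putative interneurons and excluded: essentially all
#' inhibitory cells (PV, SOM, VIP) have kurtosis below 15 while the sparse
#' transients of pyramidal cells score far above it.
#'
#' @param kurtosis_value Kurtosis from [trace_kurtosis()].
#' @param threshold Decision threshold (default 15).
#' @return Logical: `TRUE` for putative excitatory (kept).  Undefined
#'   kurtosis classifies as `FALSE`.
#' @export
classify_putative_excitatory <- function(kurtosis_value, threshold = 15) {
  if (threshold <= 0) abort("threshold must be > 0")
  !is.na(kurtosis_value) & kurtosis_value >= threshold
}

#' Preprocess raw ROI traces into inferred spikes
#'
#' Runs the full signal-extraction chain on every ROI: neuropil
#' correction, noise estimation, constrained non-negative deconvolution,
#' and kurtosis-based classification.
#'
#' @param raw,neuropil Matrices, frames x ROIs.
#' @param imaging_rate_hz Frame rate.
#' @param tau_half_ms Indicator half-decay time (default 135 ms).
#' @param n_knots Spline knots for the drifting baseline.
#' @param kurtosis_threshold Threshold of
#'   [classify_putative_excitatory()].
#' @param cells Optional tibble of cell geometry carried through (one row
#'   per ROI).
#'
#' @return An object of class `trace_set`: matrices `corrected`,
#'   `spikes`, `drift`; per-ROI `noise_sigma`, `kurtosis`,
#'   `putative_excitatory`, `deconv_feasible`; the `cells` tibble;
#'   `imaging_rate_hz` and `gamma`.
#' @export
preprocess_traces <- function(raw, neuropil, imaging_rate_hz = 15.5,
                              tau_half_ms = 135, n_knots = 10,
                              kurtosis_threshold = 15, cells = NULL) {
  raw <- as.matrix(raw); neuropil <- as.matrix(neuropil)
  stopifnot(all(dim(raw) == dim(neuropil)))
  n <- ncol(raw)
  gam <- ar1_decay(tau_half_ms, imaging_rate_hz)
  corrected <- neuropil_correct(raw, neuropil)
  spikes <- matrix(0, nrow(raw), n)
  drift <- matrix(0, nrow(raw), n)
  noise_sigma <- kurt <- numeric(n)
  feasible <- logical(n)
  for (j in seq_len(n)) {
    y <- corrected[, j]
    noise_sigma[j] <- estimate_noise(y)
    d <- deconvolve(y, gam, max(noise_sigma[j], 1e-12), n_knots)
    spikes[, j] <- d$spikes
    drift[, j] <- d$drift
    feasible[j] <- d$feasible
    kurt[j] <- trace_kurtosis(y)
  }
  colnames(spikes) <- colnames(raw)
  structure(
    list(
      corrected = corrected, spikes = spikes, drift = drift,
      noise_sigma = noise_sigma, kurtosis = kurt,
      putative_excitatory = classify_putative_excitatory(
        kurt, kurtosis_threshold),
      deconv_feasible = feasible,
      cells = cells, imaging_rate_hz = imaging_rate_hz, gamma = gam
    ),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "<trace_set> %d ROIs x %d frames, %d putative excitatory, gamma %.3f\n",
    ncol(x$spikes), nrow(x$spikes), sum(x$putative_excitatory), x$gamma
  ))
  invisible(x)
}

#' Per-cell quality-control table of a trace set
#'
#' @param ts A `trace_set`.
#' @return A tibble with one row per ROI: noise, kurtosis, classification
#'   and deconvolution feasibility, joined to cell geometry when present.
#' @export
qc_table <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  qc <- tibble(
    roi = seq_along(ts$noise_sigma),
    noise_sigma = ts$noise_sigma,
    kurtosis = ts$kurtosis,
    putative_excitatory = ts$putative_excitatory,
    deconv_feasible = ts$deconv_feasible
  )
  if (!is.null(ts$cells)) qc <- bind_cols(ts$cells, qc[-1])
  qc
}
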