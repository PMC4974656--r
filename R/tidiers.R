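#' Tidy an exponential decay fit
#'
#' @param x An `exp_decay_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate` and (for the
#'   length constant) the bootstrap confidence bounds.
#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble(
    term = c("amplitude", "length_constant_um", "asymptote"),
    estimate = c(x$amplitude, x$length_constant_um, x$asymptote),
    conf.low = c(NA, x$ci95_lambda[1], NA),
    conf.high = c(NA, x$ci95_lambda[2], NA)
  )
}

#' @rdname tidy.exp_decay_fit
#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble(
    length_constant_um = x$length_constant_um,
    ci_low = x$ci95_lambda[1], ci_high = x$ci95_lambda[2],
    amplitude = x$amplitude, asymptote = x$asymptote,
    identifiable = x$identifiable, n_boot = x$n_boot, rss = x$rss
  )
}

#' Tidy a set of fitted kernels
#'
#' @param x A `kernel_fit_set`.
#' @param ... Unused.
#' @return The per-cell summary tibble (`r_L`, selected penalty,
#'   preferred orientation/spatial frequency, significance).
#' @export
tidy.kernel_fit_set <- function(x, ...) as_tibble(x$summary)

#' @rdname tidy.kernel_fit_set
#' @export
glance.kernel_fit_set <- function(x, ...) {
  tibble(
    n_cells = nrow(x$summary),
    n_significant = sum(x$summary$significant),
    median_r_L = median(x$summary$r_L, na.rm = TRUE),
    r_L_threshold = x$config$r_L_threshold
  )
}

#' Plot a similarity-distance curve
#'
#' Bin means with s.e.m. error bars against cortical distance; point
#' size encodes the rank-sum significance of each bin against the
#' rightmost bin.
#'
#' @param object A `similarity_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.similarity_curve <- function(object, ...) {
  df <- as_tibble(object)
  df$significance <- -log10(pmax(df$ranksum_p_vs_last, 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 4, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$significance)) +
    ggplot2::scale_size_continuous(name = "-log10 p", range = c(1, 4)) +
    ggplot2::labs(x = "cortical distance (µm)",
                  y = "tuning similarity (r)") +
    ggplot2::theme_classic()
}

#' Plot an exponential decay fit over its curve
#'
#' @param object An `exp_decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exp_decay_fit <- function(object, ...) {
  p <- autoplot(object$curve)
  d <- seq(0, max(object$curve$bin_hi), length.out = 200)
  fit_df <- tibble(
    bin_mid = d,
    mean = object$asymptote +
      object$amplitude * exp(-d / object$length_constant_um)
  )
  p + ggplot2::geom_line(data = fit_df, colour = "red", linetype = "dashed")
}

#' Display a fitted kernel on the full Fourier plane
#'
#' Symmetrizes a phase-pooled kernel back to the full `(kx, ky)` plane
#' (origin in the middle) and renders it as a raster, normalized to unit
#' peak absolute value.
#'
#' @param w Kernel vector on the folded grid.
#' @param design The `stimulus_design` the kernel was fit against.
#' @return A ggplot.
#' @export
plot_kernel <- function(w, design) {
  df <- symmetrize_kernel(w / max(abs(w)), design)
  ggplot2::ggplot(df, ggplot2::aes(.data$kx, .data$ky, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "w") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(omega[x]), y = expression(omega[y])) +
    ggplot2::theme_minimal()
}
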