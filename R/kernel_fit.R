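#' Configuration of the separable kernel fit
#'
#' @param n_lags Temporal lags of the response model (default 8, about
#'   0.5 s at 15.5 Hz).
#' @param penalty_grid Log-spaced candidate strengths of the kernel
#'   smoothness penalty, searched by cross-validation.
#' @param n_folds Cross-validation folds (contiguous time blocks,
#'   default 5).
#' @param max_als_iters Maximum alternating-least-squares iterations.
#' @param tol Relative decrease of the penalized objective below which
#'   ALS stops.
#' @param r_L_threshold Model-selection threshold on the `r_L` statistic
#'   (default 0.15).
#'
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_lags = 8,
                       penalty_grid = 10^seq(-0.5, 2.5, by = 1),
                       n_folds = 5,
                       max_als_iters = 30,
                       tol = 1e-5,
                       r_L_threshold = 0.15) {
  if (any(penalty_grid <= 0)) abort("penalty_grid values must be > 0")
  if (n_folds < 2) abort("n_folds must be >= 2")
  structure(
    list(n_lags = as.integer(n_lags), penalty_grid = sort(penalty_grid),
         n_folds = as.integer(n_folds), max_als_iters = max_als_iters,
         tol = tol, r_L_threshold = r_L_threshold),
    class = "fit_config"
  )
}

#' Baseline (stimulus-free) model fit
#'
#' Least-squares fit of `y(t) = b + a * r(t)`: a rest offset plus a
#' locomotion offset.  Its residual sum of squares is the reference
#' against which the stimulus model is judged.
#'
#' @param y Response vector (inferred spikes).
#' @param running 0/1 locomotion indicator, same length.
#' @return List with `b`, `a`, `sse_baseline`.
#' @export
fit_baseline <- function(y, running) {
  if (length(y) != length(running)) abort("y and running lengths differ")
  if (var(running) == 0) {
    b <- mean(y); a <- 0
  } else {
    a <- cov(y, running) / var(running)
    b <- mean(y) - a * mean(running)
  }
  list(b = b, a = a, sse_baseline = sum((y - b - a * running)^2))
}

#' Goodness-of-fit statistic of the stimulus model
#'
#' `r_L = sqrt(max(0, 1 - sse_model / sse_baseline))`, with `sse_model`
#' the cross-validated sum of squared errors of the stimulus model and
#' `sse_baseline` that of the stimulus-free baseline.  The statistic is
#' analogous to a Pearson correlation between model prediction and
#' response; a fit is deemed significant when `r_L` exceeds the selection
#' threshold.
#'
#' @param sse_model Cross-validated SSE of the full model.
#' @param sse_baseline SSE of the baseline model (> 0).
#' @return `r_L` in `[0, 1]`, or `NA` with a warning when the baseline
#'   SSE is zero.
#' @export
r_L_statistic <- function(sse_model, sse_baseline) {
  if (sse_baseline <= 0) {
    warn("sse_baseline is zero: r_L undefined")
    return(NA_real_)
  }
  sqrt(pmax(0, 1 - sse_model / sse_baseline))
}

#' Peak orientation and spatial frequency of a kernel
#'
#' Location of the kernel maximum on the grid; the spatial frequency of
#' that cell is the "peak spatial frequency" used by the sharp-tuning
#' robustness filter.  Phase pooling makes the peak identical on the
#' folded and the symmetrized full plane.
#'
#' @param w Kernel vector over the grid cells.
#' @param grid Grid tibble (`design$grid`).
#' @return List with `pref_orientation_deg` and `pref_sf_cpd`; both `NA`
#'   (with a warning) for a constant kernel.
#' @export
kernel_peak <- function(w, grid) {
  if (max(w) - min(w) == 0) {
    warn("constant kernel: peak undefined")
    return(list(pref_orientation_deg = NA_real_, pref_sf_cpd = NA_real_))
  }
  i <- which.max(w)
  list(pref_orientation_deg = grid$orientation_deg[i],
       pref_sf_cpd = grid$sf_cpd[i])
}

# ---- sufficient statistics of the design ----------------------------------
#
# The ALS normal equations only need cross-products of the lagged one-hot
# stimulus indicators, which are independent of the cell.  With S_i the
# frames x grid indicator at lag i - 1:
#   S_i' S_i = diag(N1[, i])                     (one-hot columns)
#   S_i' S_j + S_j' S_i = E_ij  (i < j),  stored flattened as one column
#     of `Emat` so that both ALS half-steps reduce to a single dense
#     matrix-vector product:
#   A'A  = sum_{i<j} v_i v_j E_ij + diag(sum_i v_i^2 N1[, i])
#   U'U[i, j] = w' S_i' S_j w = 0.5 * w' E_ij w
# Statistics are accumulated per CV block and combined, so fitting many
# cells against one design reuses all of this.

design_context <- function(design, running, n_folds) {
  T_ <- length(design$frame_cond)
  L <- design$n_lags
  G <- nrow(design$grid)
  cond_lags <- vapply(seq_len(L) - 1L,
                      function(tau) lagged_cond(design$frame_cond, tau),
                      integer(T_))
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  fold <- as.integer(cut(seq_len(T_), breaks = n_folds, labels = FALSE))
  blocks <- lapply(seq_len(n_folds), function(k) {
    block_stats(cond_lags, running, which(fold == k), G, L, pairs)
  })
  total <- Reduce(add_stats, blocks)
  trains <- lapply(blocks, function(b) sub_stats(total, b))
  test_frames <- lapply(blocks, function(b) b$frames)
  list(T_ = T_, L = L, G = G, cond_lags = cond_lags, fold = fold,
       running = running, pairs = pairs,
       total = total, trains = trains, test_frames = test_frames,
       penalty_matrix = kernel_penalty_matrix(design))
}

block_stats <- function(cond_lags, running, frames, G, L, pairs) {
  cl <- cond_lags[frames, , drop = FALSE]
  r <- running[frames]
  N1 <- Nr <- matrix(0, G, L)
  for (i in seq_len(L)) {
    ci <- cl[, i]
    ok <- ci > 0
    N1[, i] <- tabulate2(ci[ok], G)
    Nr[, i] <- tabulate2(ci[ok], G, r[ok])
  }
  Emat <- matrix(0, G * G, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ci <- cl[, pairs[p, 1]]; cj <- cl[, pairs[p, 2]]
    keep <- ci > 0 & cj > 0
    D <- Matrix::sparseMatrix(i = ci[keep], j = cj[keep], x = 1,
                              dims = c(G, G))
    Emat[, p] <- as.vector(as.matrix(D + Matrix::t(D)))
  }
  list(Emat = Emat, N1 = N1, Nr = Nr, n = length(frames),
       sr = sum(r), srr = sum(r^2), frames = frames)
}

tabulate2 <- function(idx, nbins, wt = NULL) {
  if (is.null(wt)) return(tabulate(idx, nbins))
  out <- numeric(nbins)
  if (length(idx)) {
    agg <- rowsum(wt, idx)
    out[as.integer(rownames(agg))] <- agg
  }
  out
}

add_stats <- function(a, b) {
  list(Emat = a$Emat + b$Emat, N1 = a$N1 + b$N1, Nr = a$Nr + b$Nr,
       n = a$n + b$n, sr = a$sr + b$sr, srr = a$srr + b$srr,
       frames = sort(c(a$frames, b$frames)))
}

sub_stats <- function(a, b) {
  list(Emat = a$Emat - b$Emat, N1 = a$N1 - b$N1, Nr = a$Nr - b$Nr,
       n = a$n - b$n, sr = a$sr - b$sr, srr = a$srr - b$srr,
       frames = setdiff(a$frames, b$frames))
}

# per-cell response statistics on a frame subset
cell_stats <- function(ctx, y, frames) {
  cl <- ctx$cond_lags[frames, , drop = FALSE]
  yF <- y[frames]; rF <- ctx$running[frames]
  M <- matrix(0, ctx$G, ctx$L)
  for (tau in seq_len(ctx$L)) {
    ci <- cl[, tau]
    ok <- ci > 0
    M[, tau] <- tabulate2(ci[ok], ctx$G, yF[ok])
  }
  list(M = M, sy = sum(yF), syy = sum(yF^2), syr = sum(yF * rF))
}

# squared discrete Laplacian on the folded grid with reflecting boundaries
kernel_penalty_matrix <- function(design) {
  grid <- design$grid
  G <- nrow(grid)
  key <- function(kx, ky) paste(kx, ky)
  lut <- setNames(seq_len(G), key(grid$kx, grid$ky))
  ii <- jj <- integer(0)
  deg <- integer(G)
  for (g in seq_len(G)) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nk <- grid$kx[g] + d[1]; nl <- grid$ky[g] + d[2]
      if (nk == 0 && nl == 0) next                      # DC excluded
      if (nk < 0 || (nk == 0 && nl < 0)) { nk <- -nk; nl <- -nl }
      h <- lut[key(nk, nl)]
      if (!is.na(h)) { ii <- c(ii, g); jj <- c(jj, h); deg[g] <- deg[g] + 1L }
    }
  }
  Lp <- Matrix::sparseMatrix(i = ii, j = jj, x = -1, dims = c(G, G)) +
    Matrix::Diagonal(G, deg)
  as.matrix(Matrix::crossprod(Lp))
}

# ---- alternating least squares --------------------------------------------

#' Alternating least squares fit of the separable response model
#'
#' Fits `y(t) = sum_g sum_tau w(g) v(tau) s(g, t - tau) + b + a r(t)` by
#' block coordinate descent: given the temporal kernel `v`, the spatial
#' kernel `w` (jointly with the offsets `b`, `a`) solves a least-squares
#' problem with a quadratic smoothness penalty (squared discrete
#' Laplacian on the Fourier grid); given `w`, the temporal kernel (again
#' jointly with the offsets) solves an unpenalized least-squares problem.
#' Iterations stop when the penalized objective decreases by less than
#' `tol` relative, or at `max_als_iters` (then flagged unconverged).  At
#' convergence `v` is normalized to unit norm with the scale exchanged
#' into `w` (recorded as `scale`) and its sign fixed so the
#' largest-magnitude lag is positive; normalizing inside the loop would
#' rescale the penalty term and void the descent guarantee.
#'
#' Initialization: `v` is a delta at lag 2 frames, and the first `w`
#' comes from one unpenalized regression given that `v`.  A vanishing
#' ridge (1e-8 of the mean diagonal) stabilizes each solve against the
#' near-collinearity of the kernel mean with the intercept.
#'
#' @param y Response vector (inferred spikes).
#' @param design A `stimulus_design`.
#' @param running 0/1 locomotion indicator per frame.
#' @param penalty Smoothness penalty strength.
#' @param config A [fit_config()].
#' @param ctx,ystats,stats Precomputed design/cell statistics (used by
#'   the cross-validation driver); leave `NULL` to compute from the
#'   inputs.
#'
#' @return A list of class `kernel_fit`: `w`, `v` (unit norm), `b`, `a`,
#'   `penalty`, `objective`, `objective_trace` (one value per half-step),
#'   `converged`.
#' @export
als_fit <- function(y, design, running, penalty, config = fit_config(),
                    ctx = NULL, ystats = NULL, stats = NULL) {
  if (is.null(ctx)) {
    ctx <- design_context(design, running, config$n_folds)
  }
  if (is.null(stats)) stats <- ctx$total
  if (is.null(ystats)) ystats <- cell_stats(ctx, y, stats$frames)
  P <- ctx$penalty_matrix
  G <- ctx$G; L <- ctx$L
  pairs <- ctx$pairs
  ridge <- 1e-8

  build_AtA <- function(v) {
    cvec <- v[pairs[, 1]] * v[pairs[, 2]]
    AtA <- matrix(stats$Emat %*% cvec, G, G)
    diag(AtA) <- diag(AtA) + as.numeric(stats$N1 %*% v^2)
    AtA
  }

  # penalized LS for (w, b, a) given v; returns theta and the objective
  # J = 0.5 * ||y - X theta||^2 + 0.5 * penalty * w' P w  (ridge included)
  solve_w <- function(v, lam) {
    AtA <- build_AtA(v)
    At1 <- as.numeric(stats$N1 %*% v)
    Atr <- as.numeric(stats$Nr %*% v)
    Aty <- as.numeric(ystats$M %*% v)
    rw <- ridge * mean(diag(AtA))
    XtX <- rbind(
      cbind(AtA + lam * P + rw * diag(G), At1, Atr),
      c(At1, stats$n + rw, stats$sr),
      c(Atr, stats$sr, stats$srr + rw)
    )
    Xty <- c(Aty, ystats$sy, ystats$syr)
    th <- solve(XtX, Xty)
    list(w = th[seq_len(G)], b = th[G + 1], a = th[G + 2],
         obj = 0.5 * (ystats$syy - sum(th * Xty)))
  }

  solve_v <- function(w) {
    ww <- tcrossprod(w)
    UtU <- matrix(0, L, L)
    off <- 0.5 * as.numeric(crossprod(stats$Emat, as.vector(ww)))
    UtU[pairs] <- off
    UtU[pairs[, c(2, 1), drop = FALSE]] <- off
    diag(UtU) <- as.numeric(w^2 %*% stats$N1)
    Ut1 <- as.numeric(w %*% stats$N1)
    Utr <- as.numeric(w %*% stats$Nr)
    Uty <- as.numeric(w %*% ystats$M)
    rv <- ridge * mean(diag(UtU))
    XtX <- rbind(cbind(UtU + rv * diag(L), Ut1, Utr),
                 c(Ut1, stats$n + rv, stats$sr),
                 c(Utr, stats$sr, stats$srr + rv))
    Xty <- c(Uty, ystats$sy, ystats$syr)
    th <- solve(XtX, Xty)
    list(v = th[seq_len(L)], b = th[L + 1], a = th[L + 2],
         obj_fit = 0.5 * (ystats$syy - sum(th * Xty)))
  }

  # init: delta temporal kernel at lag 2 frames, one unpenalized regression.
  # The unit-norm constraint on v is enforced at the end (scale exchanged
  # with w): renormalizing inside the loop would rescale the penalty term
  # and break the strict monotonicity of block coordinate descent.
  v <- numeric(L); v[min(3L, L)] <- 1
  init <- solve_w(v, 0)
  w <- unname(init$w); b <- init$b; a <- init$a
  pen_w <- function(w) 0.5 * penalty * as.numeric(w %*% (P %*% w))
  obj <- init$obj + pen_w(w)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_als_iters)) {
    vs <- solve_v(w)
    v <- vs$v; b <- vs$b; a <- vs$a
    trace <- c(trace, vs$obj_fit + pen_w(w))
    ws <- solve_w(v, penalty)
    w <- ws$w; b <- ws$b; a <- ws$a
    obj_new <- ws$obj
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= config$tol * max(1, abs(obj))) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  nv <- sqrt(sum(v^2))
  if (nv > 0) {
    flip <- sign(v[which.max(abs(v))])
    v <- flip * v / nv
    w <- flip * w * nv
  }
  structure(
    list(w = unname(w), v = unname(v), b = unname(b), a = unname(a),
         penalty = penalty, objective = obj, scale = nv,
         objective_trace = trace, converged = converged),
    class = "kernel_fit"
  )
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf(
    "<kernel_fit> %d grid cells x %d lags, penalty %.3g, %s\n",
    length(x$w), length(x$v), x$penalty,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

# prediction on a set of frames from (w, v, b, a)
predict_frames <- function(ctx, fit, frames) {
  cl <- ctx$cond_lags[frames, , drop = FALSE]
  w0 <- c(0, fit$w)
  pred <- rep(fit$b, length(frames)) + fit$a * ctx$running[frames]
  for (tau in seq_len(ctx$L)) {
    pred <- pred + fit$v[tau] * w0[cl[, tau] + 1L]
  }
  pred
}

#' Choose the kernel smoothness penalty by cross-validation
#'
#' Fivefold cross-validation over contiguous time blocks (respecting the
#' temporal autocorrelation of calcium signals): for each penalty in the
#' grid the model is fit on the training blocks and scored on the
#' held-out block.  Selection follows the one-standard-error convention:
#' the largest (smoothest) penalty whose summed held-out SSE lies within
#' one between-fold standard error of the minimum, so noise cells are
#' driven to heavy smoothing while clean tuned cells keep a light touch;
#' exact ties likewise resolve towards the larger penalty.
#'
#' @inheritParams als_fit
#' @param config A [fit_config()] (penalty grid, folds).
#'
#' @return List: `penalty` (selected), `cv_sse` (named vector over the
#'   grid), `sse_model` (pooled held-out SSE at the selected penalty).
#' @export
cross_validate_penalty <- function(y, design, running, config = fit_config(),
                                   ctx = NULL) {
  if (is.null(ctx)) ctx <- design_context(design, running, config$n_folds)
  grid <- config$penalty_grid
  cv <- matrix(0, length(grid), config$n_folds)
  for (k in seq_len(config$n_folds)) {
    train <- ctx$trains[[k]]
    ytrain <- cell_stats(ctx, y, train$frames)
    test_frames <- ctx$test_frames[[k]]
    ytest <- y[test_frames]
    for (p in seq_along(grid)) {
      fit <- als_fit(y, NULL, NULL, grid[p], config,
                     ctx = ctx, ystats = ytrain, stats = train)
      cv[p, k] <- sum((ytest - predict_frames(ctx, fit, test_frames))^2)
    }
  }
  tot <- rowSums(cv)
  # one-standard-error rule: the largest penalty whose summed held-out SSE
  # is within one (between-fold) standard error of the minimum; exact ties
  # also resolve towards the larger penalty
  imin <- which.min(tot)
  se <- stats::sd(cv[imin, ]) * sqrt(config$n_folds)
  best <- max(which(tot <= tot[imin] + se))
  list(penalty = grid[best],
       cv_sse = setNames(tot, format(grid)),
       sse_model = tot[best])
}

#' Fit the separable tuning model to every cell
#'
#' Runs, per cell: the baseline fit, penalty selection by
#' cross-validation, the final ALS fit on all frames at the selected
#' penalty, the `r_L` statistic (cross-validated model SSE against the
#' baseline SSE), and the kernel peak.
#'
#' @param spikes Matrix of inferred spikes, frames x cells.
#' @param design A `stimulus_design`.
#' @param running 0/1 locomotion indicator per frame.
#' @param config A [fit_config()].
#' @param cells Optional cell-geometry tibble (row per column of
#'   `spikes`) carried into the summary.
#'
#' @return An object of class `kernel_fit_set`: `summary` tibble (one row
#'   per cell: `r_L`, `penalty`, `pref_orientation_deg`, `pref_sf_cpd`,
#'   `significant`, SSEs, offsets), `W` (grid x cells kernel matrix),
#'   `V` (lags x cells), the `design` and `config`.
#' @export
fit_kernels <- function(spikes, design, running, config = fit_config(),
                        cells = NULL) {
  spikes <- as.matrix(spikes)
  n <- ncol(spikes)
  ctx <- design_context(design, running, config$n_folds)
  W <- matrix(0, ctx$G, n)
  V <- matrix(0, ctx$L, n)
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    y <- spikes[, j]
    base <- fit_baseline(y, running)
    cvres <- cross_validate_penalty(y, design, running, config, ctx = ctx)
    fit <- als_fit(y, design, running, cvres$penalty, config, ctx = ctx)
    W[, j] <- fit$w
    V[, j] <- fit$v
    r_L <- r_L_statistic(cvres$sse_model, base$sse_baseline)
    peak <- kernel_peak(fit$w, design$grid)
    rows[[j]] <- tibble(
      cell = j,
      r_L = r_L,
      significant = !is.na(r_L) & r_L >= config$r_L_threshold,
      penalty = cvres$penalty,
      pref_orientation_deg = peak$pref_orientation_deg,
      pref_sf_cpd = peak$pref_sf_cpd,
      sse_model = cvres$sse_model,
      sse_baseline = base$sse_baseline,
      b = fit$b, a = fit$a,
      converged = fit$converged
    )
  }
  summary <- bind_rows(rows)
  if (!is.null(cells)) {
    stopifnot(nrow(cells) == n)
    cells <- as_tibble(cells)
    clash <- intersect(names(cells), names(summary))
    names(cells)[match(clash, names(cells))] <- paste0("true_", clash)
    summary <- bind_cols(cells, summary[setdiff(names(summary), "cell")])
  }
  structure(
    list(summary = summary, W = W, V = V, design = design, config = config),
    class = "kernel_fit_set"
  )
}

#' @export
print.kernel_fit_set <- function(x, ...) {
  cat(sprintf(
    "<kernel_fit_set> %d cells, %d significant (r_L >= %g)\n",
    nrow(x$summary), sum(x$summary$significant), x$config$r_L_threshold
  ))
  invisible(x)
}

#' Select significant cells and accept or reject the field
#'
#' Keeps cells whose `r_L` meets the threshold; the imaging field enters
#' the clustering analysis only if the number of kept cells exceeds
#' `min_cells`.
#'
#' @param fits A `kernel_fit_set`.
#' @param r_L_threshold Selection threshold (default 0.15, inclusive).
#' @param min_cells Minimum kept-cell count for field acceptance
#'   (strictly exceeded; default 20).
#'
#' @return A list of class `field_selection`: `accepted`, `kept` (row
#'   indices into the fit summary), `n_kept`, and the filtered `fits`.
#' @export
select_cells <- function(fits, r_L_threshold = 0.15, min_cells = 20) {
  stopifnot(inherits(fits, "kernel_fit_set"))
  keep <- which(!is.na(fits$summary$r_L) &
                  fits$summary$r_L >= r_L_threshold)
  sub <- fits
  sub$summary <- fits$summary[keep, ]
  sub$W <- fits$W[, keep, drop = FALSE]
  sub$V <- fits$V[, keep, drop = FALSE]
  structure(
    list(accepted = length(keep) > min_cells, kept = keep,
         n_kept = length(keep), fits = sub),
    class = "field_selection"
  )
}

#' @export
print.field_selection <- function(x, ...) {
  cat(sprintf("<field_selection> %d cells kept; field %s\n",
              x$n_kept, if (x$accepted) "ACCEPTED" else "rejected"))
  invisible(x)
}
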