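#' Tuning similarity of two kernels
#'
#' Pearson correlation of the flattened Fourier-plane kernels.  The
#' correlation compares the whole shape of the joint orientation and
#' spatial-frequency profile, peak location and bandwidth alike.
#'
#' @param w1,w2 Kernel vectors on the same grid.
#' @return Correlation in `[-1, 1]`; constant kernels raise an error
#'   (such pairs are dropped upstream).
#' @export
tuning_similarity <- function(w1, w2) {
  if (length(w1) != length(w2)) abort("kernels live on different grids")
  if (sd(w1) == 0 || sd(w2) == 0) abort("constant kernel: similarity undefined")
  cor(w1, w2)
}

#' Cortical distance between two cells
#'
#' The in-plane distance is the Euclidean distance between the
#' projections of the two cell bodies onto the cortical surface (the
#' imaging plane is parallel to it); the depth difference is the absolute
#' difference of the plane depths.
#'
#' @param cell1,cell2 Numeric vectors `c(x_um, y_um, depth_um)` or
#'   one-row data frames with those columns.
#' @return List with `d_um` and `delta_depth_um`.
#' @export
cortical_distance <- function(cell1, cell2) {
  as_xyz <- function(p) {
    if (is.data.frame(p)) c(p$x_um, p$y_um, p$depth_um) else as.numeric(p)
  }
  p1 <- as_xyz(cell1); p2 <- as_xyz(cell2)
  if (!all(is.finite(c(p1, p2)))) abort("positions must be finite")
  list(d_um = sqrt((p1[1] - p2[1])^2 + (p1[2] - p2[2])^2),
       delta_depth_um = abs(p1[3] - p2[3]))
}

#' Absolute difference between two preferred orientations
#'
#' Orientations live on a 180-degree circle, so the difference is
#' `min(|d|, 180 - |d|)`, always in `[0, 90]`.
#'
#' @param ori1,ori2 Orientations in degrees (vectorized).
#' @return Differences in degrees.
#' @examples
#' orientation_difference(10, 170)  # 20
#' @export
orientation_difference <- function(ori1, ori2) {
  d <- abs(ori1 - ori2) %% 180
  pmin(d, 180 - d)
}

#' Wilcoxon rank-sum test
#'
#' Thin wrapper with the conventions used throughout the clustering
#' analysis: the p-value is exact (by enumeration over rank arrangements)
#' whenever the pooled sample size is at most 12 and there are no ties,
#' and otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` (x tends smaller) or
#'   `"greater"`.
#' @param method `"auto"` (the rule above), or force `"exact"` /
#'   `"normal"`.
#' @return The p-value.
#' @examples
#' ranksum_test(c(1, 2), c(3, 4), "less")  # 1/6
#' @export
ranksum_test <- function(x, y, alternative = "two.sided",
                         method = c("auto", "exact", "normal")) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  method <- match.arg(method)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(method,
    auto = length(x) + length(y) <= 12 && !ties,
    exact = TRUE,
    normal = FALSE
  )
  suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)$p.value
  )
}

#' Build the table of all cell pairs
#'
#' Forms every unordered pair of cells within a field and records the
#' in-plane cortical distance, depth difference, tuning similarity
#' (Pearson correlation of the kernels), absolute preferred-orientation
#' difference and absolute log2 preferred-spatial-frequency difference.
#' When a `field` column is present, pairs never span fields: pair
#' statistics are within-field and then pooled.
#'
#' @param cells Tibble with one row per cell: `x_um`, `y_um`, `depth_um`,
#'   optionally `pref_orientation_deg`, `pref_sf_cpd` and `field`.
#' @param W Kernel matrix, grid cells x cells (columns follow `cells`
#'   rows).
#'
#' @return A tibble of class `pair_table`: `cell_i`, `cell_j`, `d_um`,
#'   `delta_depth_um`, `similarity`, and (when preferences are present)
#'   `d_ori_deg`, `d_log_sf`.  Pairs with a constant kernel are dropped
#'   (count in attribute `n_dropped`).
#' @export
pair_table <- function(cells, W) {
  W <- as.matrix(W)
  stopifnot(nrow(cells) == ncol(W))
  n <- nrow(cells)
  if (n < 2) abort("need at least two cells")
  const <- apply(W, 2, sd) == 0
  sim <- suppressWarnings(cor(W))
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  if ("field" %in% names(cells)) {
    same <- cells$field[i] == cells$field[j]
    i <- i[same]; j <- j[same]
  }
  out <- tibble(
    cell_i = i, cell_j = j,
    d_um = sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                  (cells$y_um[i] - cells$y_um[j])^2),
    delta_depth_um = abs(cells$depth_um[i] - cells$depth_um[j]),
    similarity = sim[cbind(i, j)]
  )
  if ("pref_orientation_deg" %in% names(cells)) {
    out$d_ori_deg <- orientation_difference(cells$pref_orientation_deg[i],
                                            cells$pref_orientation_deg[j])
  }
  if ("pref_sf_cpd" %in% names(cells)) {
    out$d_log_sf <- abs(log2(cells$pref_sf_cpd[i] / cells$pref_sf_cpd[j]))
  }
  dropped <- const[out$cell_i] | const[out$cell_j] | is.na(out$similarity)
  if (any(dropped)) {
    message(sum(dropped), " pairs dropped (constant kernel)")
    out <- out[!dropped, ]
  }
  attr(out, "n_dropped") <- sum(dropped)
  class(out) <- c("pair_table", class(out))
  out
}

#' Bin tuning similarity by cortical distance
#'
#' Groups pairs into distance bins and reports per-bin mean, s.e.m.,
#' median and pair count, together with a one-sided rank-sum p-value
#' comparing each bin's similarities against those of the rightmost bin
#' (testing whether nearby pairs are more similar than pairs about 200 um
#' apart).  The rightmost bin is assigned p = 1 by convention.
#'
#' @param pairs A `pair_table`.
#' @param bin_edges Increasing bin edges in um; default 7 bins of 30 um
#'   covering 0-210 um.
#'
#' @return A tibble of class `similarity_curve`: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `n_pairs`, `mean`, `sem`, `median`, `ranksum_p_vs_last`.
#'   Empty bins carry `NA` statistics.
#' @export
bin_similarity <- function(pairs, bin_edges = seq(0, 210, by = 30)) {
  if (length(bin_edges) < 3) abort("need at least 2 bins")
  if (is.unsorted(bin_edges, strictly = TRUE)) abort("bin_edges must increase")
  nb <- length(bin_edges) - 1
  bin <- findInterval(pairs$d_um, bin_edges, rightmost.closed = TRUE)
  inb <- bin >= 1 & bin <= nb
  bin <- bin[inb]; simv <- pairs$similarity[inb]
  groups <- split(simv, factor(bin, levels = seq_len(nb)))
  last_nonempty <- max(which(vapply(groups, length, 1L) > 0))
  ref <- groups[[last_nonempty]]
  rows <- lapply(seq_len(nb), function(k) {
    g <- groups[[k]]
    if (!length(g)) {
      return(tibble(bin_lo = bin_edges[k], bin_hi = bin_edges[k + 1],
                    bin_mid = (bin_edges[k] + bin_edges[k + 1]) / 2,
                    n_pairs = 0L, mean = NA_real_, sem = NA_real_,
                    median = NA_real_, ranksum_p_vs_last = NA_real_))
    }
    p <- if (k == last_nonempty) 1 else ranksum_test(g, ref, "greater")
    tibble(bin_lo = bin_edges[k], bin_hi = bin_edges[k + 1],
           bin_mid = (bin_edges[k] + bin_edges[k + 1]) / 2,
           n_pairs = length(g), mean = mean(g),
           sem = sd(g) / sqrt(length(g)), median = median(g),
           ranksum_p_vs_last = p)
  })
  out <- bind_rows(rows)
  attr(out, "bin_edges") <- bin_edges
  class(out) <- c("similarity_curve", class(out))
  out
}

#' Exponential decay fit of the similarity-distance curve
#'
#' Least-squares fit of `mean_similarity(d) = c + A * exp(-d / lambda)`
#' to the bin means, with a multi-start search over initial length
#' constants.  When raw pairs are supplied, a percentile bootstrap
#' (resampling pairs, rebinning, refitting) gives the 95% confidence
#' interval of the length constant, propagating pair-level noise into
#' the binned fit.
#'
#' @param x A `pair_table` (enables the bootstrap) or a
#'   `similarity_curve`.
#' @param bin_edges Distance bins used when `x` is a pair table.
#' @param n_boot Bootstrap replicates (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @param lambda_starts Multi-start grid of initial length constants, um.
#'
#' @return An object of class `exp_decay_fit`: `amplitude`,
#'   `length_constant_um`, `asymptote`, `ci95_lambda`, `identifiable`,
#'   `n_boot`, `seed`, the fitted `curve`, and the bootstrap draws.  A
#'   flat curve (amplitude indistinguishable from zero) is flagged
#'   `identifiable = FALSE` with the CI spanning the start grid.
#' @export
fit_exponential_decay <- function(x, bin_edges = seq(0, 210, by = 30),
                                  n_boot = 200, seed = 1,
                                  lambda_starts = c(10, 20, 40, 80, 160)) {
  is_pairs <- inherits(x, "pair_table") ||
    (!inherits(x, "similarity_curve") && !is.null(x$similarity))
  curve <- if (is_pairs) bin_similarity(x, bin_edges) else x
  pt <- fit_decay_once(curve, lambda_starts)
  boot_lambda <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (!pt$identifiable) {
    ci <- range(lambda_starts)
  } else if (is_pairs && n_boot > 0) {
    set.seed(seed)
    boot_lambda <- rep(NA_real_, n_boot)
    np <- nrow(x)
    for (b in seq_len(n_boot)) {
      bs <- x[sample.int(np, np, replace = TRUE), ]
      bc <- bin_similarity(bs, bin_edges)
      bf <- tryCatch(
        fit_decay_once(bc, unique(c(pt$lambda, lambda_starts))),
        error = function(e) NULL
      )
      if (!is.null(bf) && bf$identifiable) boot_lambda[b] <- bf$lambda
    }
    ok <- boot_lambda[!is.na(boot_lambda)]
    if (length(ok) >= 20) {
      ci <- unname(quantile(ok, c(0.025, 0.975)))
      ci <- c(min(ci[1], pt$lambda), max(ci[2], pt$lambda))
    }
  }
  structure(
    list(amplitude = pt$A, length_constant_um = pt$lambda,
         asymptote = pt$c0, ci95_lambda = ci,
         identifiable = pt$identifiable, n_boot = n_boot, seed = seed,
         curve = curve, boot_lambdas = boot_lambda, rss = pt$rss),
    class = "exp_decay_fit"
  )
}

# single multi-start nonlinear fit to the bin means
fit_decay_once <- function(curve, lambda_starts) {
  ok <- !is.na(curve$mean)
  d <- curve$bin_mid[ok]; m <- curve$mean[ok]
  if (sum(ok) < 4) abort("need at least 4 bins with data")
  best <- NULL
  for (l0 in lambda_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        m ~ c0 + A * exp(-d / lambda),
        start = list(c0 = min(m), A = max(m) - min(m) + 1e-6, lambda = l0),
        lower = c(-Inf, -Inf, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      cf <- coef(fit)
      best <- list(c0 = unname(cf["c0"]), A = unname(cf["A"]),
                   lambda = unname(cf["lambda"]), rss = rss)
    }
  }
  if (is.null(best)) abort("exponential fit did not converge from any start")
  spread <- max(m) - min(m)
  best$identifiable <- abs(best$A) > max(1e-8, 1e-3 * spread) &&
    best$lambda < 10 * max(d)
  best
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_decay_fit> lambda = %.1f um (95%% CI %.1f-%.1f), A = %.3f, c = %.3f%s\n",
    x$length_constant_um, x$ci95_lambda[1], x$ci95_lambda[2],
    x$amplitude, x$asymptote,
    if (x$identifiable) "" else " [NOT identifiable]"
  ))
  invisible(x)
}

#' Near-versus-far preference difference test
#'
#' One-sided rank-sum test that preference differences (orientation or
#' log spatial frequency) of nearby pairs (closer than `near_um`) are
#' smaller than those of distant pairs (farther than `far_um`).  This
#' checks that clustering is visible in the preferences themselves, not
#' only in whole-kernel similarity.
#'
#' @param pairs A `pair_table`.
#' @param near_um,far_um Distance cut-offs (default 50 / 150 um).
#' @param field Which difference to test: `"d_ori_deg"` or `"d_log_sf"`.
#' @return List: `p`, `n_near`, `n_far`.
#' @export
near_far_preference_test <- function(pairs, near_um = 50, far_um = 150,
                                     field = c("d_ori_deg", "d_log_sf")) {
  field <- match.arg(field)
  if (!field %in% names(pairs)) abort(paste("pair table lacks", field))
  near <- pairs[[field]][pairs$d_um < near_um]
  far <- pairs[[field]][pairs$d_um > far_um]
  if (!length(near) || !length(far)) abort("empty near or far group")
  list(p = ranksum_test(near, far, "less"),
       n_near = length(near), n_far = length(far))
}

#' Similarity-distance correlation within one field
#'
#' Pearson correlation between tuning similarity and cortical distance
#' over the pairs of a single imaging field, with a one-sided p-value for
#' a negative correlation.
#'
#' Pairs that share a cell are not independent, so the naive t-based
#' p-value is anti-conservative (a Mantel-test situation).  When the pair
#' table carries its cell indices, the p-value therefore comes from a
#' permutation null that relabels cells (shuffling the distance structure
#' against the similarity structure), which is exactly calibrated under
#' the hypothesis that tuning is independent of position.  For bare pair
#' lists without cell indices the parametric t p-value is used.
#'
#' @param pairs A `pair_table` from one field (>= 3 pairs).
#' @param method `"auto"` (permutation when cell indices are present,
#'   else t), `"permutation"`, or `"t"`.
#' @param n_perm Permutations for the Mantel-style null.
#' @param seed Optional RNG seed for the permutation draw; by default the
#'   caller's RNG stream is used (and never reset).  When a seed is given
#'   the global RNG state is restored afterwards.
#' @return List with `r`, `p` and the `method` used.
#' @export
per_field_correlation <- function(pairs, method = c("auto", "permutation", "t"),
                                  n_perm = 199, seed = NULL) {
  method <- match.arg(method)
  if (nrow(pairs) < 3) abort("need at least 3 pairs")
  if (sd(pairs$similarity) == 0 || sd(pairs$d_um) == 0) {
    abort("zero variance: correlation undefined")
  }
  has_ids <- all(c("cell_i", "cell_j") %in% names(pairs))
  if (method == "auto") method <- if (has_ids) "permutation" else "t"
  if (method == "permutation" && !has_ids) {
    abort("permutation test needs cell_i/cell_j columns")
  }
  r_obs <- cor(pairs$similarity, pairs$d_um)
  if (method == "t") {
    ct <- cor.test(pairs$similarity, pairs$d_um, alternative = "less")
    return(list(r = unname(ct$estimate), p = ct$p.value, method = "t"))
  }
  ids <- sort(unique(c(pairs$cell_i, pairs$cell_j)))
  m <- length(ids)
  i <- match(pairs$cell_i, ids)
  j <- match(pairs$cell_j, ids)
  D <- matrix(NA_real_, m, m)
  D[cbind(i, j)] <- pairs$d_um
  D[cbind(j, i)] <- pairs$d_um
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
      get(".Random.seed", envir = .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
  }
  r_perm <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(m)
    dp <- D[cbind(p[i], p[j])]
    ok <- !is.na(dp)
    cor(pairs$similarity[ok], dp[ok])
  }, 0)
  p <- (1 + sum(r_perm <= r_obs)) / (n_perm + 1)
  list(r = r_obs, p = p, method = "permutation")
}

#' Tuning similarity by distance and depth
#'
#' Splits pairs by depth difference (one group per plane separation,
#' e.g. 0/40/80/120 um) and bins each group by in-plane distance as in
#' [bin_similarity()].  Above-chance similarity at large depth
#' separations indicates columnar organization.
#'
#' @param pairs A `pair_table`.
#' @param depth_levels Depth separations to analyse, um.
#' @param bin_edges In-plane distance bins.
#' @return Named list of `similarity_curve`s (class
#'   `depth_similarity`), one per available depth level; missing levels
#'   are reported and omitted.
#' @export
depth_similarity_analysis <- function(pairs, depth_levels = c(0, 40, 80, 120),
                                      bin_edges = seq(0, 210, by = 30)) {
  present <- depth_levels[depth_levels %in% unique(pairs$delta_depth_um)]
  if (length(present) < 2) abort("need pairs at >= 2 depth separations")
  if (length(present) < length(depth_levels)) {
    message("no pairs at depth separation(s): ",
            paste(setdiff(depth_levels, present), collapse = ", "))
  }
  out <- lapply(present, function(dd) {
    bin_similarity(pairs[pairs$delta_depth_um == dd, ], bin_edges)
  })
  names(out) <- paste0("delta_", present)
  structure(out, class = "depth_similarity")
}

#' Robustness filters on the analysed cell set
#'
#' The three control filters applied before re-running the clustering
#' analysis: keep only high-kurtosis cells (putative excitatory), only
#' sharply tuned cells (peak spatial frequency above 0.025 cpd), or only
#' the largest 80% of ROIs (excluding likely dendritic fragments).
#'
#' @param cells Tibble with, as needed, `kurtosis`, `pref_sf_cpd`,
#'   `roi_area_um2` and `cell_id`.
#' @param mode One of `"kurtosis_ge_15"`, `"peak_sf_gt_0.025"`,
#'   `"roi_top_80pct"`.
#' @return The filtered tibble (attribute `kept` holds the row indices).
#' @export
robustness_filter <- function(cells,
                              mode = c("kurtosis_ge_15", "peak_sf_gt_0.025",
                                       "roi_top_80pct")) {
  mode <- match.arg(mode)
  keep <- switch(mode,
    kurtosis_ge_15 = which(!is.na(cells$kurtosis) & cells$kurtosis >= 15),
    peak_sf_gt_0.025 = which(!is.na(cells$pref_sf_cpd) &
                               cells$pref_sf_cpd > 0.025),
    roi_top_80pct = {
      n_drop <- floor(0.2 * nrow(cells))
      id <- if ("cell_id" %in% names(cells)) cells$cell_id else seq_len(nrow(cells))
      ord <- order(cells$roi_area_um2, id)   # smallest first, ties by id
      sort(setdiff(seq_len(nrow(cells)), ord[seq_len(n_drop)]))
    }
  )
  if (!length(keep)) abort(paste("filter", mode, "removed every cell"))
  out <- cells[keep, ]
  attr(out, "kept") <- keep
  attr(out, "filter_mode") <- mode
  out
}
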