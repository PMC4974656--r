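# Independent dense oracle for the constrained deconvolution program:
#   min sum(s)  s.t.  s >= 0,  ||y - C s - B beta||_2 <= sigma * sqrt(T)
# solved through its Lagrangian with a dense QP (quadprog) per penalty and
# an outer bisection driving the residual to the noise budget.  Shares no
# code with the package's pool-adjacent-violators solver.
deconv_oracle <- function(y, gamma, sigma, n_knots = 10) {
  T_ <- length(y)
  C <- outer(seq_len(T_), seq_len(T_),
             function(i, j) ifelse(i >= j, gamma^(i - j), 0))
  B <- saltpepper:::drift_basis(T_, n_knots)
  X <- cbind(C, B)
  k <- ncol(B)
  D <- crossprod(X) + diag(c(rep(1e-10, T_), rep(1e-8, k)))
  Amat <- rbind(diag(T_), matrix(0, k, T_))
  target <- sigma^2 * T_

  solve_pen <- function(lam) {
    d <- crossprod(X, y) - c(rep(lam, T_), rep(0, k))
    sol <- quadprog::solve.QP(D, d, Amat, rep(0, T_))
    s <- pmax(sol$solution[seq_len(T_)], 0)
    beta <- sol$solution[T_ + seq_len(k)]
    rss <- sum((y - C %*% s - B %*% beta)^2)
    list(s = s, rss = rss)
  }

  f0 <- solve_pen(0)
  if (f0$rss > target * (1 + 1e-9)) {
    return(list(objective = sum(f0$s), feasible = FALSE))
  }
  lo <- 0; sol_lo <- f0
  hi <- max(sd(y), sigma)
  fh <- solve_pen(hi)
  tries <- 0
  while (fh$rss <= target && tries < 60) {
    lo <- hi; sol_lo <- fh
    hi <- hi * 4
    fh <- solve_pen(hi)
    tries <- tries + 1
  }
  if (fh$rss > target) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      fm <- solve_pen(mid)
      if (fm$rss <= target) { lo <- mid; sol_lo <- fm } else hi <- mid
    }
  } else {
    sol_lo <- fh
  }
  list(objective = sum(sol_lo$s), feasible = TRUE, spikes = sol_lo$s)
}

# random feasible test traces for the oracle comparison
random_trace <- function(T_, gamma, seed) {
  set.seed(seed)
  spk <- rpois(T_, 0.15) * runif(T_, 0.5, 1.5)
  ca <- as.numeric(stats::filter(spk, gamma, method = "recursive"))
  drift <- 0.5 * sin(seq(0, 2, length.out = T_) + runif(1, 0, 6))
  ca + drift + rnorm(T_, 0, 0.1)
}
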