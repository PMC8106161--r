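# Independent oracles used to check the package's implementations.
# Each is written directly from the textbook definition of the quantity it
# computes and shares no code with the implementation under test.

# One-component PLS1 (NIPALS) with unit-variance scaling: the reference the
# O-PLS fit must reduce to when no orthogonal components are removed.
oracle_pls1_predict <- function(x, y, xnew = x) {
  cm <- colMeans(x)
  cs <- apply(x, 2, sd)
  cs[cs == 0] <- 1
  xs <- sweep(sweep(x, 2, cm, "-"), 2, cs, "/")
  yc <- y - mean(y)
  w <- crossprod(xs, yc)
  w <- w / sqrt(sum(w^2))
  t1 <- xs %*% w
  b <- sum(t1 * yc) / sum(t1^2)
  xnew_s <- sweep(sweep(xnew, 2, cm, "-"), 2, cs, "/")
  as.numeric(xnew_s %*% w) * b + mean(y)
}

# First-component NIPALS PLS between two multivariate blocks (X scores).
oracle_pls2_xscore <- function(x, y, tol = 1e-28, max_iter = 20000) {
  xs <- scale(x)
  ys <- scale(y)
  u <- ys[, 1]
  for (i in seq_len(max_iter)) {
    w <- crossprod(xs, u)
    w <- w / sqrt(sum(w^2))
    t1 <- xs %*% w
    cvec <- crossprod(ys, t1)
    cvec <- cvec / sqrt(sum(cvec^2))
    u_new <- ys %*% cvec
    if (sum((u_new - u)^2) < tol) break
    u <- u_new
  }
  as.numeric(t1)
}

# Step-up Benjamini-Hochberg from the definition:
# adjusted_(i) = min_{j >= i} p_(j) * m / j, clipped at 1, in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# PERMANOVA pseudo-F via the centroid-free partitioning, written
# independently from sums over pairs (total and within-group).
oracle_permanova_f <- function(d, groups) {
  m <- as.matrix(d)^2
  n <- nrow(m)
  lev <- unique(groups)
  sst <- sum(m) / (2 * n)
  ssw <- 0
  for (g in lev) {
    i <- which(groups == g)
    ssw <- ssw + sum(m[i, i]) / (2 * length(i))
  }
  a <- length(lev)
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# Penalized Mnet objective on the standardized scale (1/(2n) loss).
oracle_mnet_objective <- function(beta, gz, xs, zc, yc, lambda1, lambda2, gamma) {
  r <- yc - xs %*% beta - if (ncol(zc)) zc %*% gz else 0
  mcp <- ifelse(abs(beta) <= gamma * lambda1,
    lambda1 * abs(beta) - beta^2 / (2 * gamma),
    gamma * lambda1^2 / 2
  )
  sum(r^2) / (2 * length(yc)) + sum(mcp) + lambda2 / 2 * sum(beta^2)
}

# Derivative-free global minimization of the Mnet objective by Nelder-Mead
# restarted from several points (feasible for p + q <= 8).
oracle_mnet_minimize <- function(xs, zc, yc, lambda1, lambda2, gamma, starts) {
  p <- ncol(xs)
  q <- ncol(zc)
  fn <- function(par) {
    oracle_mnet_objective(
      par[seq_len(p)], par[p + seq_len(q)],
      xs, zc, yc, lambda1, lambda2, gamma
    )
  }
  best <- NULL
  for (s in starts) {
    fit <- optim(s, fn, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
    fit <- optim(fit$par, fn, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

# Partial Spearman by explicit rank + linear-model residualization.
oracle_partial_spearman <- function(x, y, z_numeric) {
  rx <- rank(x)
  ry <- rank(y)
  if (is.null(z_numeric) || ncol(z_numeric) == 0) {
    return(cor(rx, ry))
  }
  ex <- residuals(lm(rx ~ z_numeric))
  ey <- residuals(lm(ry ~ z_numeric))
  cor(ex, ey)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_stat <- function(ia) {
    av <- pooled[ia]
    bv <- pooled[-ia]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  obs <- u_stat(seq_len(na))
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, u_stat)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Upper-tail hypergeometric by direct summation of the pmf.
oracle_hypergeom_tail <- function(k, big_k, n_sel, big_n) {
  kk <- k:min(big_k, n_sel)
  sum(choose(big_k, kk) * choose(big_n - big_k, n_sel - kk)) / choose(big_n, n_sel)
}

# Procrustes RMS after optimal translation/rotation/reflection (no scaling
# of shape beyond the least-squares scale factor is needed for the
# classical-scaling identity check, so none is applied).
procrustes_rms <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  s <- svd(crossprod(b, a))
  rot <- s$u %*% t(s$v)
  sqrt(mean((a - b %*% rot)^2))
}
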