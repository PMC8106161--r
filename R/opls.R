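# Single-response orthogonal projections to latent structures (O-PLS).
#
# The model separates variation in X predictive of y from variation
# orthogonal to y: orthogonal components are extracted and removed first
# (w_o proportional to p - (w'p) w), then a single predictive PLS component
# is fitted on the deflated matrix.

# Lean fitting core shared by the user-facing fit, the cross-validation loop
# and the permutation engine. `x` and `y` are raw; centering/scaling happens
# here so CV folds re-estimate it.
opls_core <- function(x, y, n_orth, scaling = "uv") {
  sc <- scale_matrix(x, scaling)
  xs <- sc$x
  y_mean <- mean(y)
  yc <- y - y_mean

  p_feat <- ncol(xs)
  w_orth <- matrix(0, p_feat, n_orth)
  p_orth <- matrix(0, p_feat, n_orth)
  t_orth <- matrix(0, nrow(xs), n_orth)
  if (n_orth > 0) {
    for (i in seq_len(n_orth)) {
      w <- crossprod(xs, yc)
      w <- w / sqrt(sum(w^2))
      tt <- xs %*% w
      pp <- crossprod(xs, tt) / sum(tt^2)
      wo <- pp - c(crossprod(w, pp)) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) {
        # no orthogonal variation left; keep zero component
        break
      }
      wo <- wo / nwo
      to <- xs %*% wo
      po <- crossprod(xs, to) / sum(to^2)
      xs <- xs - tcrossprod(to, po)
      w_orth[, i] <- wo
      p_orth[, i] <- po
      t_orth[, i] <- to
    }
  }
  w <- crossprod(xs, yc)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) abort("X carries no covariance with y; predictive weight undefined.")
  w <- w / nw
  tt <- xs %*% w
  pp <- crossprod(xs, tt) / sum(tt^2)
  b <- c(crossprod(tt, yc) / crossprod(tt, tt))
  resid <- yc - tt * b
  r2y <- 1 - sum(resid^2) / sum(yc^2)

  list(
    w = c(w), t = c(tt), p = c(pp), b = b,
    w_orth = w_orth, t_orth = t_orth, p_orth = p_orth,
    center = sc$center, scale = sc$scale, y_mean = y_mean,
    r2y = r2y, n_orth = n_orth, scaling = scaling
  )
}

opls_core_predict <- function(core, xnew) {
  xs <- sweep(sweep(xnew, 2, core$center, "-"), 2, core$scale, "/")
  if (ncol(core$w_orth) > 0) {
    for (i in seq_len(ncol(core$w_orth))) {
      to <- xs %*% core$w_orth[, i, drop = FALSE]
      xs <- xs - tcrossprod(to, core$p_orth[, i, drop = FALSE])
    }
  }
  c(xs %*% core$w) * core$b + core$y_mean
}

prepare_xy <- function(x, y, min_n = 3) {
  x <- as_feature_matrix(x)
  check_no_na(x, "x")
  check_no_na(y, "y")
  if (length(y) != nrow(x)) abort("`y` must have one value per row of `x`.")
  if (nrow(x) < min_n) abort(sprintf("At least %d samples required.", min_n))
  if (sd(y) == 0) abort("`y` is constant; no model can be fitted.")
  s <- col_sds(x)
  if (any(s == 0)) {
    warn(sprintf("Dropping %d zero-variance feature(s).", sum(s == 0)))
    x <- x[, s > 0, drop = FALSE]
  }
  if (ncol(x) == 0) abort("No non-constant features left in `x`.")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  list(x = x, y = as.numeric(y))
}

resolve_n_orth <- function(x, y, n_orth, scaling) {
  if (identical(n_orth, "auto")) {
    # add orthogonal components while LOO Q2Y improves by more than 0.01
    best_k <- 0
    best_q2 <- q2_cv(x, y, n_orth = 0, scaling = scaling)
    k <- 1
    max_k <- min(nrow(x) - 3, ncol(x) - 1)
    while (k <= max_k) {
      q2 <- try(q2_cv(x, y, n_orth = k, scaling = scaling), silent = TRUE)
      if (inherits(q2, "try-error") || q2 - best_q2 <= 0.01) break
      best_q2 <- q2
      best_k <- k
      k <- k + 1
    }
    return(best_k)
  }
  n_orth
}

#' Fit a single-response O-PLS model
#'
#' After centering and scaling X, `n_orth` components orthogonal to the
#' response are iteratively extracted and removed, then one predictive PLS
#' component is fitted. With `n_orth = 0` the model coincides with
#' 1-component PLS1.
#'
#' @param x Samples-by-features matrix, data frame or [omics_block()].
#' @param y Numeric response, one value per sample.
#' @param n_orth Number of orthogonal components (default 1), or `"auto"` to
#'   add components while leave-one-out Q2Y improves by more than 0.01.
#' @param scaling Feature scaling: `"uv"` (unit variance, default),
#'   `"pareto"` or `"none"` (centering always applied).
#' @param q2 Compute leave-one-out Q2Y (default `TRUE`; set `FALSE` inside
#'   tight loops).
#' @return An object of class `opls_model` with predictive weights `w`,
#'   scores `t`, loadings `p`, regression scalar `b`, orthogonal parts
#'   (`w_orth`, `t_orth`, `p_orth`), scaling parameters, `R2Y` and `Q2Y`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x[, 1] + rnorm(20, sd = 0.1)
#' fit <- fit_opls(x, y, n_orth = 0)
#' glance(fit)
fit_opls <- function(x, y, n_orth = 1, scaling = c("uv", "pareto", "none"),
                     q2 = TRUE) {
  scaling <- match.arg(scaling)
  d <- prepare_xy(x, y)
  n_orth <- resolve_n_orth(d$x, d$y, n_orth, scaling)
  if (n_orth < 0) abort("`n_orth` must be a nonnegative integer.")
  rank_x <- qr(scale_matrix(d$x, scaling)$x)$rank
  if (n_orth >= rank_x) {
    abort(sprintf("`n_orth` (%d) must be below rank(X) = %d.", n_orth, rank_x))
  }
  core <- opls_core(d$x, d$y, n_orth, scaling)
  core$feature_ids <- colnames(d$x)
  core$n <- nrow(d$x)
  core$q2y <- if (q2 && nrow(d$x) >= 4) q2_cv(d$x, d$y, n_orth, scaling) else NA_real_
  core$x <- d$x
  core$y <- d$y
  class(core) <- "opls_model"
  core
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> n = %d, features = %d, orthogonal components = %d\n  R2Y = %.4f, Q2Y = %s\n",
    x$n, length(x$w), x$n_orth, x$r2y,
    ifelse(is.na(x$q2y), "not computed", sprintf("%.4f", x$q2y))
  ))
  invisible(x)
}

#' Predict from an O-PLS model
#'
#' Applies the training centering/scaling, removes orthogonal variation with
#' the stored orthogonal weights/loadings, projects onto the predictive
#' weight and back-transforms to the response scale. Named feature columns
#' are matched to the training features, so predictions are invariant to
#' feature order.
#'
#' @param object An `opls_model`.
#' @param newdata Samples-by-features matrix or data frame with the training
#'   features.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  xnew <- as_feature_matrix(newdata, "newdata")
  if (!is.null(colnames(xnew))) {
    missing <- setdiff(object$feature_ids, colnames(xnew))
    if (length(missing)) {
      abort(sprintf("`newdata` lacks training feature(s): %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    xnew <- xnew[, object$feature_ids, drop = FALSE]
  } else if (ncol(xnew) != length(object$w)) {
    abort("`newdata` has the wrong number of features.")
  }
  opls_core_predict(object, xnew)
}

# Cross-validated Q2Y; folds = "loo" or an integer k. Scaling is
# re-estimated inside each training fold.
q2_cv <- function(x, y, n_orth, scaling = "uv", folds = "loo", seed = 1) {
  n <- nrow(x)
  assign <- if (identical(folds, "loo")) seq_len(n) else make_folds(n, folds, seed)
  press <- 0
  for (f in unique(assign)) {
    test <- assign == f
    core <- opls_core(x[!test, , drop = FALSE], y[!test], n_orth, scaling)
    pred <- opls_core_predict(core, x[test, , drop = FALSE])
    press <- press + sum((y[test] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Leave-one-out cross-validated Q2Y
#'
#' `Q2Y = 1 - PRESS / SS_tot`, where PRESS accumulates squared
#' leave-one-out prediction errors and SS_tot is the total sum of squares of
#' `y` about its mean. Centering and scaling are re-estimated inside each
#' fold.
#'
#' @inheritParams fit_opls
#' @return The Q2Y scalar (`<= 1`; negative when the model predicts worse
#'   than the mean).
#' @export
q2_loocv <- function(x, y, n_orth = 1, scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  d <- prepare_xy(x, y, min_n = 4)
  q2_cv(d$x, d$y, n_orth, scaling, folds = "loo")
}

#' Permutation validation of an O-PLS model
#'
#' The response is permuted `n_permutations` times under a fixed seed; the
#' model and its cross-validated Q2Y are recomputed for each permutation.
#' P-values use the +1-smoothed estimator
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)` and therefore never
#' return 0.
#'
#' @inheritParams fit_opls
#' @param n_permutations Number of response permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param cv Cross-validation used for Q2Y inside the test: `"loo"`
#'   (default) or an integer number of folds (faster for large n).
#' @return An object of class `opls_permutation` with observed `R2Y`/`Q2Y`,
#'   null vectors `null_r2y`/`null_q2y` and p-values `p_r2y`/`p_q2y`.
#' @export
permutation_test <- function(x, y, n_orth = 1, n_permutations = 1000,
                             seed = 1, scaling = c("uv", "pareto", "none"),
                             cv = "loo") {
  scaling <- match.arg(scaling)
  if (n_permutations < 1) abort("`n_permutations` must be at least 1.")
  d <- prepare_xy(x, y, min_n = 4)
  obs_r2 <- opls_core(d$x, d$y, n_orth, scaling)$r2y
  obs_q2 <- q2_cv(d$x, d$y, n_orth, scaling, folds = cv, seed = seed)
  null_r2 <- numeric(n_permutations)
  null_q2 <- numeric(n_permutations)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      yp <- sample(d$y)
      null_r2[b] <- opls_core(d$x, yp, n_orth, scaling)$r2y
      null_q2[b] <- q2_cv(d$x, yp, n_orth, scaling, folds = cv, seed = seed)
    }
  })
  structure(
    list(
      r2y = obs_r2, q2y = obs_q2,
      null_r2y = null_r2, null_q2y = null_q2,
      p_r2y = (1 + sum(null_r2 >= obs_r2)) / (1 + n_permutations),
      p_q2y = (1 + sum(null_q2 >= obs_q2)) / (1 + n_permutations),
      n_permutations = n_permutations, seed = seed
    ),
    class = "opls_permutation"
  )
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf(
    "O-PLS permutation test (%d permutations)\n  R2Y = %.4f (p = %.4g), Q2Y = %.4f (p = %.4g)\n",
    x$n_permutations, x$r2y, x$p_r2y, x$q2y, x$p_q2y
  ))
  invisible(x)
}

#' Variable importance in projection
#'
#' The predictive-component VIP: for the single predictive component,
#' `VIP_j = sqrt(p) * |w_j|` with `||w|| = 1`, so `mean(VIP^2) = 1` exactly.
#' The `"total"` variant additionally folds in the orthogonal components,
#' weighting each component's squared weights by the X-variance it explains.
#'
#' @param model A fitted `opls_model`.
#' @param variant `"predictive"` (default) or `"total"`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model, variant = c("predictive", "total")) {
  variant <- match.arg(variant)
  if (!inherits(model, "opls_model")) abort("`model` must be an opls_model.")
  p_feat <- length(model$w)
  if (variant == "predictive" || model$n_orth == 0) {
    v <- sqrt(p_feat) * abs(model$w)
  } else {
    ssx <- c(sum(model$t^2) * sum(model$p^2))
    w2 <- model$w^2 * ssx
    for (i in seq_len(ncol(model$w_orth))) {
      sso <- sum(model$t_orth[, i]^2) * sum(model$p_orth[, i]^2)
      w2 <- w2 + model$w_orth[, i]^2 * sso
      ssx <- ssx + sso
    }
    v <- sqrt(p_feat * w2 / ssx)
  }
  setNames(v, model$feature_ids)
}

#' Select features from an O-PLS model by VIP and FDR
#'
#' Per-feature significance is the two-sided correlation test (t
#' distribution, `df = n - 2`) of the feature against the predictive score,
#' BH-adjusted across features. A feature is selected when `pFDR <
#' fdr_primary`, or when `pFDR < fdr_relaxed` and its VIP exceeds `vip_cut`.
#'
#' @param x The training data used to fit `model`.
#' @param y The training response.
#' @param model A fitted `opls_model`.
#' @param fdr_primary Reference FDR threshold (default 0.05).
#' @param fdr_relaxed Relaxed FDR threshold applied to high-VIP features
#'   (default 0.10).
#' @param vip_cut VIP threshold for the relaxed rule (default 1).
#' @return A tibble with columns `feature_id`, `loading_corr`, `vip`,
#'   `p.value`, `p_fdr`, `selected`.
#' @export
select_features <- function(x, y, model, fdr_primary = 0.05,
                            fdr_relaxed = 0.10, vip_cut = 1.0) {
  if (!inherits(model, "opls_model")) abort("`model` must be an opls_model.")
  xm <- as_feature_matrix(x)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(ncol(xm)))
  xm <- xm[, model$feature_ids, drop = FALSE]
  n <- nrow(xm)
  tt <- model$t
  r <- as.vector(cor(xm, tt))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p_fdr <- p.adjust(p, method = "BH")
  v <- unname(vip(model))
  tibble(
    feature_id = model$feature_ids,
    loading_corr = r,
    vip = v,
    p.value = p,
    p_fdr = p_fdr,
    selected = p_fdr < fdr_primary | (p_fdr < fdr_relaxed & v > vip_cut)
  )
}
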