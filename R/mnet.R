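# Mnet penalized regression: minimax concave penalty (MCP) combined with a
# ridge term, fitted by cyclic coordinate descent with covariates left
# unpenalized. Loss convention: (1/(2n)) ||y - X beta - Z gamma||^2 +
# sum_j MCP(beta_j; lambda1, gamma) + (lambda2/2) ||beta||^2, with X
# standardized internally to mean 0 and 1/n-variance 1, and lambda1 =
# alpha * lambda, lambda2 = (1 - alpha) * lambda.

#' Univariate Mnet thresholding operator
#'
#' Closed-form minimizer of
#' `1/2 (z - b)^2 + MCP(b; lambda1, gamma) + lambda2/2 b^2`:
#' the soft-threshold `S(z, lambda1) / (1 + lambda2 - 1/gamma)` inside the
#' MCP region `|z| <= gamma * lambda1 * (1 + lambda2)`, and the ridge
#' solution `z / (1 + lambda2)` outside it. Requires
#' `gamma * (1 + lambda2) > 1`, the condition for the univariate subproblem
#' to be convex.
#'
#' @param z Numeric vector of unpenalized coordinate solutions.
#' @param lambda1 MCP level (`>= 0`).
#' @param lambda2 Ridge level (`>= 0`).
#' @param gamma MCP concavity parameter (`> 1`).
#' @return The thresholded value(s).
#' @export
#' @examples
#' mnet_threshold(1.5, lambda1 = 1, lambda2 = 0, gamma = 3)  # 0.75
#' mnet_threshold(3, lambda1 = 1, lambda2 = 0, gamma = 3)    # 3
mnet_threshold <- function(z, lambda1, lambda2, gamma) {
  if (lambda1 < 0 || lambda2 < 0) abort("Penalty levels must be nonnegative.")
  if (gamma * (1 + lambda2) <= 1) {
    abort("Non-convex subproblem: need gamma * (1 + lambda2) > 1.")
  }
  soft <- sign(z) * pmax(abs(z) - lambda1, 0)
  ifelse(
    abs(z) <= gamma * lambda1 * (1 + lambda2),
    soft / (1 + lambda2 - 1 / gamma),
    z / (1 + lambda2)
  )
}

mcp_penalty <- function(beta, lambda1, gamma) {
  b <- abs(beta)
  ifelse(b <= gamma * lambda1,
    lambda1 * b - b^2 / (2 * gamma),
    gamma * lambda1^2 / 2
  )
}

# Penalized objective on the standardized scale (used by tests and the
# debug monotonicity check).
mnet_objective <- function(beta_std, gamma_z, xs, zc, yc, lambda1, lambda2, gamma) {
  r <- yc - xs %*% beta_std - if (ncol(zc)) zc %*% gamma_z else 0
  sum(r^2) / (2 * length(yc)) +
    sum(mcp_penalty(beta_std, lambda1, gamma)) +
    lambda2 / 2 * sum(beta_std^2)
}

prepare_mnet <- function(x, y, covariates) {
  x <- as_feature_matrix(x)
  check_no_na(x, "x")
  check_no_na(y, "y")
  n <- nrow(x)
  if (length(y) != n) abort("`y` must have one value per row of `x`.")
  z <- if (is.null(covariates)) {
    matrix(numeric(0), n, 0)
  } else {
    zm <- covariate_numeric(covariates, n)
    zm
  }
  center <- colMeans(x)
  sds <- sqrt(colMeans(x^2) - center^2) # 1/n variance, ncvreg convention
  if (any(sds == 0)) abort("Constant feature(s) in `x`; remove before fitting.")
  xs <- sweep(sweep(x, 2, center, "-"), 2, sds, "/")
  z_center <- if (ncol(z)) colMeans(z) else numeric(0)
  zc <- if (ncol(z)) sweep(z, 2, z_center, "-") else z
  list(
    xs = xs, zc = zc, yc = y - mean(y), y_mean = mean(y),
    x_center = center, x_scale = sds, z_center = z_center,
    feature_ids = colnames(x) %||% paste0("x", seq_len(ncol(x))),
    covariate_ids = colnames(z) %||% character(0)
  )
}

# Covariates as a numeric design (factors dummy-encoded, not standardized).
covariate_numeric <- function(covariates, n) {
  if (is.matrix(covariates)) {
    storage.mode(covariates) <- "double"
    return(covariates)
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) abort("Covariates must have one row per sample.")
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(as.numeric(v), ncol = 1)
      colnames(m) <- nm
      m
    } else {
      f <- factor(v)
      m <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
      m
    }
  })
  do.call(cbind, cols)
}

#' Fit an Mnet (MCP + ridge) regression
#'
#' Cyclic coordinate descent over standardized penalized features using
#' [mnet_threshold()], with covariates updated by unpenalized least-squares
#' coordinate steps. The split `lambda1 = alpha * lambda`,
#' `lambda2 = (1 - alpha) * lambda` follows the elastic-net mixing
#' convention (`alpha` near 1: concave/sparse-dominant; near 0:
#' ridge-dominant). Penalized coefficients are back-transformed to the
#' original feature scale.
#'
#' @param x Samples-by-features matrix or data frame (penalized part).
#' @param y Numeric response.
#' @param covariates Optional data frame/matrix of unpenalized covariates
#'   (factors dummy-encoded).
#' @param lambda Overall penalty level (`>= 0`).
#' @param alpha Mixing parameter in `(0, 1]`.
#' @param gamma MCP concavity (`> 1`).
#' @param max_iter,tol Convergence controls: stop when the largest
#'   standardized-coefficient change in a sweep falls below `tol`.
#' @param debug If `TRUE`, assert that the penalized objective never
#'   increases across sweeps.
#' @return An object of class `mnet_fit` with `intercept`, `covariate_coef`,
#'   `beta` (original scale), `beta_std`, the penalty parameters and
#'   convergence diagnostics.
#' @export
fit_mnet <- function(x, y, covariates = NULL, lambda, alpha = 0.5, gamma = 3,
                     max_iter = 10000, tol = 1e-7, debug = FALSE) {
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  if (gamma <= 1) abort("`gamma` must exceed 1.")
  d <- prepare_mnet(x, y, covariates)
  lambda1 <- alpha * lambda
  lambda2 <- (1 - alpha) * lambda
  if (gamma * (1 + lambda2) <= 1) {
    abort("Invalid (gamma, alpha, lambda): gamma * (1 + lambda2) must exceed 1.")
  }
  fit <- mnet_cd(d, lambda1, lambda2, gamma, max_iter, tol, debug = debug)
  if (!fit$converged) {
    abort(
      sprintf(
        "Coordinate descent did not converge in %d sweeps (last max change %.3g).",
        max_iter, fit$max_change
      ),
      class = "ferromics_nonconvergence",
      fit = fit
    )
  }
  beta <- fit$beta_std / d$x_scale
  intercept <- d$y_mean - sum(beta * d$x_center) -
    if (length(d$z_center)) sum(fit$gamma_z * d$z_center) else 0
  structure(
    list(
      intercept = intercept,
      covariate_coef = setNames(fit$gamma_z, d$covariate_ids),
      beta = setNames(beta, d$feature_ids),
      beta_std = setNames(fit$beta_std, d$feature_ids),
      lambda = lambda, alpha = alpha, gamma = gamma,
      iterations = fit$iterations, max_change = fit$max_change,
      converged = fit$converged
    ),
    class = "mnet_fit"
  )
}

# Inner coordinate-descent engine on a prepared problem; supports warm starts.
mnet_cd <- function(d, lambda1, lambda2, gamma, max_iter, tol,
                    beta_init = NULL, gamma_init = NULL, debug = FALSE) {
  xs <- d$xs
  zc <- d$zc
  yc <- d$yc
  n <- length(yc)
  p <- ncol(xs)
  q <- ncol(zc)
  beta <- beta_init %||% numeric(p)
  gz <- gamma_init %||% numeric(q)
  r <- yc - if (p) xs %*% beta else 0
  if (q) r <- r - zc %*% gz
  r <- as.numeric(r)
  z_ss <- if (q) colSums(zc^2) else numeric(0)
  obj_prev <- Inf
  iter <- 0
  max_change <- Inf
  while (iter < max_iter) {
    iter <- iter + 1
    max_change <- 0
    for (m in seq_len(q)) {
      if (z_ss[m] == 0) next
      delta <- sum(zc[, m] * r) / z_ss[m]
      gz[m] <- gz[m] + delta
      r <- r - zc[, m] * delta
      max_change <- max(max_change, abs(delta))
    }
    for (j in seq_len(p)) {
      zj <- sum(xs[, j] * r) / n + beta[j]
      bj <- mnet_threshold(zj, lambda1, lambda2, gamma)
      delta <- bj - beta[j]
      if (delta != 0) {
        beta[j] <- bj
        r <- r - xs[, j] * delta
      }
      max_change <- max(max_change, abs(delta))
    }
    if (debug) {
      obj <- mnet_objective(beta, gz, xs, zc, yc, lambda1, lambda2, gamma)
      stopifnot(obj <= obj_prev + 1e-10)
      obj_prev <- obj
    }
    if (max_change < tol) break
  }
  list(
    beta_std = beta, gamma_z = gz, iterations = iter,
    max_change = max_change, converged = max_change < tol
  )
}

#' @export
print.mnet_fit <- function(x, ...) {
  cat(sprintf(
    "<mnet_fit> lambda = %.4g, alpha = %.2f, gamma = %.3g: %d of %d penalized coefficients nonzero (%d sweeps)\n",
    x$lambda, x$alpha, x$gamma, sum(x$beta != 0), length(x$beta), x$iterations
  ))
  invisible(x)
}

#' Predict from an Mnet fit
#'
#' @param object An `mnet_fit`.
#' @param newdata Feature matrix/data frame matching the training features.
#' @param covariates Covariates matching the training covariate design.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mnet_fit <- function(object, newdata, covariates = NULL, ...) {
  xm <- as_feature_matrix(newdata, "newdata")
  out <- object$intercept + as.numeric(xm %*% object$beta)
  if (length(object$covariate_coef)) {
    zm <- covariate_numeric(covariates, nrow(xm))
    out <- out + as.numeric(zm %*% object$covariate_coef)
  }
  out
}

default_lambda_path <- function(d, alpha, nlambda = 100, min_ratio = 0.001) {
  # lambda_max: smallest lambda zeroing all penalized coefficients, computed
  # on the response residualized on the (unpenalized) covariates.
  y_star <- if (ncol(d$zc)) {
    residualize(matrix(d$yc, ncol = 1), d$zc)[, 1]
  } else {
    d$yc
  }
  lmax <- max(abs(crossprod(d$xs, y_star)) / length(d$yc)) / alpha
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Cross-validated Mnet tuning
#'
#' Grid search over `(lambda, alpha, gamma)` by k-fold cross-validated mean
#' squared prediction error, with seeded fold assignment and warm starts
#' along each lambda path. Ties are broken toward the sparser model (larger
#' lambda). The winning parameters are refitted on the full data.
#'
#' @inheritParams fit_mnet
#' @param lambda Optional lambda grid; by default a 100-point log-spaced
#'   path per alpha from `lambda_max` down to `0.001 * lambda_max`.
#' @param alpha Grid of mixing values in `(0, 1]` (default
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @param gamma Grid of MCP concavities (default `c(2.5, 3, 8)`).
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param nlambda,lambda_min_ratio Path controls when `lambda` is `NULL`.
#' @return An object of class `mnet_cv`: the refitted `fit` at the optimum,
#'   `best` (a one-row tibble), and `surface` (per-grid-point CV MSE).
#' @export
cv_mnet <- function(x, y, covariates = NULL, lambda = NULL,
                    alpha = seq(0.1, 0.9, by = 0.1), gamma = c(2.5, 3, 8),
                    n_folds = 10, seed = 1, nlambda = 100,
                    lambda_min_ratio = 0.001, max_iter = 10000, tol = 1e-6) {
  if (any(alpha <= 0 | alpha > 1)) abort("`alpha` grid must lie in (0, 1].")
  if (any(gamma <= 1)) abort("`gamma` grid must exceed 1.")
  if (!is.null(lambda) && any(lambda < 0)) abort("`lambda` grid must be nonnegative.")
  d_full <- prepare_mnet(x, y, covariates)
  n <- length(d_full$yc)
  if (n < n_folds) abort("Need at least as many samples as folds.")
  folds <- make_folds(n, n_folds, seed)
  xm <- as_feature_matrix(x)
  yv <- as.numeric(y)
  zm <- if (is.null(covariates)) NULL else covariate_numeric(covariates, n)

  surface <- list()
  for (a in alpha) {
    lam_path <- if (is.null(lambda)) {
      default_lambda_path(d_full, a, nlambda, lambda_min_ratio)
    } else {
      sort(lambda, decreasing = TRUE)
    }
    for (g in gamma) {
      if (any(g * (1 + (1 - a) * lam_path) <= 1)) {
        abort("Grid contains invalid (gamma, alpha, lambda): gamma * (1 + lambda2) <= 1.")
      }
      sq_err <- matrix(0, length(lam_path), 1)
      for (f in seq_len(n_folds)) {
        test <- folds == f
        d_tr <- prepare_mnet(
          xm[!test, , drop = FALSE], yv[!test],
          if (is.null(zm)) NULL else zm[!test, , drop = FALSE]
        )
        beta_ws <- NULL
        gz_ws <- NULL
        for (li in seq_along(lam_path)) {
          l1 <- a * lam_path[li]
          l2 <- (1 - a) * lam_path[li]
          cd <- mnet_cd(d_tr, l1, l2, g, max_iter, tol,
            beta_init = beta_ws, gamma_init = gz_ws
          )
          beta_ws <- cd$beta_std
          gz_ws <- cd$gamma_z
          beta_o <- cd$beta_std / d_tr$x_scale
          icpt <- d_tr$y_mean - sum(beta_o * d_tr$x_center) -
            if (length(d_tr$z_center)) sum(cd$gamma_z * d_tr$z_center) else 0
          pred <- icpt + as.numeric(xm[test, , drop = FALSE] %*% beta_o)
          if (!is.null(zm)) {
            pred <- pred + as.numeric(zm[test, , drop = FALSE] %*% cd$gamma_z)
          }
          sq_err[li] <- sq_err[li] + sum((yv[test] - pred)^2)
        }
      }
      surface[[length(surface) + 1]] <- tibble(
        lambda = lam_path, alpha = a, gamma = g, mse = sq_err[, 1] / n
      )
    }
  }
  surface <- dplyr::bind_rows(surface)
  best <- surface |>
    dplyr::filter(.data$mse <= min(.data$mse) + 1e-12) |>
    dplyr::arrange(dplyr::desc(.data$lambda)) |>
    dplyr::slice(1)
  fit <- fit_mnet(
    xm, yv, covariates,
    lambda = best$lambda, alpha = best$alpha, gamma = best$gamma,
    max_iter = max_iter, tol = tol
  )
  structure(
    list(fit = fit, best = best, surface = surface, n_folds = n_folds, seed = seed),
    class = "mnet_cv"
  )
}

#' @export
print.mnet_cv <- function(x, ...) {
  cat(sprintf(
    "<mnet_cv> best lambda = %.4g, alpha = %.2f, gamma = %.3g (CV MSE %.4g over %d folds)\n",
    x$best$lambda, x$best$alpha, x$best$gamma, x$best$mse, x$n_folds
  ))
  print(x$fit)
  invisible(x)
}
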