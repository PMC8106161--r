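# Two-block O2-PLS: joint covariance between blocks X and Y is captured by
# the leading singular vectors of t(X) %*% Y; structured variation specific
# (orthogonal) to each block is estimated and removed before the joint part
# is re-estimated; the inner relation U ~ T B links the joint scores.

o2pls_core <- function(xs, ys, n_joint, n_xorth, n_yorth) {
  x0 <- xs
  y0 <- ys
  sv <- svd(crossprod(xs, ys), nu = n_joint, nv = n_joint)
  w <- sv$u
  cc <- sv$v

  x_orth <- list(w = NULL, t = NULL, p = NULL)
  if (n_xorth > 0) {
    wo <- matrix(0, ncol(xs), n_xorth)
    to <- matrix(0, nrow(xs), n_xorth)
    po <- matrix(0, ncol(xs), n_xorth)
    for (i in seq_len(n_xorth)) {
      tt <- xs %*% w
      e <- xs - tcrossprod(tt, w)
      u1 <- svd(crossprod(e, tt), nu = 1, nv = 0)$u
      t1 <- xs %*% u1
      p1 <- crossprod(xs, t1) / c(crossprod(t1))
      xs <- xs - tcrossprod(t1, p1)
      wo[, i] <- u1
      to[, i] <- t1
      po[, i] <- p1
      sv <- svd(crossprod(xs, ys), nu = n_joint, nv = n_joint)
      w <- sv$u
      cc <- sv$v
    }
    x_orth <- list(w = wo, t = to, p = po)
  }
  y_orth <- list(w = NULL, t = NULL, p = NULL)
  if (n_yorth > 0) {
    co <- matrix(0, ncol(ys), n_yorth)
    uo <- matrix(0, nrow(ys), n_yorth)
    qo <- matrix(0, ncol(ys), n_yorth)
    for (i in seq_len(n_yorth)) {
      uu <- ys %*% cc
      f <- ys - tcrossprod(uu, cc)
      c1 <- svd(crossprod(f, uu), nu = 1, nv = 0)$u
      u1 <- ys %*% c1
      q1 <- crossprod(ys, u1) / c(crossprod(u1))
      ys <- ys - tcrossprod(u1, q1)
      co[, i] <- c1
      uo[, i] <- u1
      qo[, i] <- q1
      sv <- svd(crossprod(xs, ys), nu = n_joint, nv = n_joint)
      w <- sv$u
      cc <- sv$v
    }
    y_orth <- list(w = co, t = uo, p = qo)
  }

  tt <- xs %*% w
  uu <- ys %*% cc
  b_t <- qr.coef(qr(tt), uu) # U ~ T B_T
  b_u <- qr.coef(qr(uu), tt) # T ~ U B_U

  ss_x <- sum(x0^2)
  ss_y <- sum(y0^2)
  r2x_joint <- sum((tt %*% t(w))^2) / ss_x
  r2y_joint <- sum((uu %*% t(cc))^2) / ss_y
  r2x_orth <- if (n_xorth > 0) sum((x_orth$t %*% t(x_orth$p))^2) / ss_x else 0
  r2y_orth <- if (n_yorth > 0) sum((y_orth$t %*% t(y_orth$p))^2) / ss_y else 0

  list(
    w = w, c = cc, t = tt, u = uu, b_t = b_t, b_u = b_u,
    x_orth = x_orth, y_orth = y_orth,
    variance = tibble(
      block = c("X", "Y"),
      joint = c(r2x_joint, r2y_joint),
      orthogonal = c(r2x_orth, r2y_orth),
      residual = c(
        1 - r2x_joint - r2x_orth,
        1 - r2y_joint - r2y_orth
      )
    )
  )
}

#' Fit a two-block O2-PLS model
#'
#' Joint weights come from the singular value decomposition of
#' `t(X) %*% Y`; per-block orthogonal components are estimated and removed
#' before the joint part is re-estimated, and the inner relation `U = T B`
#' is fitted by least squares. Each block's variance decomposes into joint,
#' orthogonal and residual parts.
#'
#' @param x,y Samples-by-features matrices/data frames/[omics_block()]s
#'   sharing samples in identical order.
#' @param n_joint Number of joint components (`>= 1`).
#' @param n_xorth,n_yorth Number of block-specific orthogonal components.
#' @param scaling Per-feature scaling (`"uv"` default; centering always).
#' @return An object of class `o2pls_model` with joint scores/loadings per
#'   block (`t`, `u`, `w`, `c`), orthogonal parts, inner-relation
#'   coefficients (`b_t`, `b_u`) and the per-block variance decomposition.
#' @export
fit_o2pls <- function(x, y, n_joint = 1, n_xorth = 0, n_yorth = 0,
                      scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  xb <- if (is_omics_block(x)) x else NULL
  yb <- if (is_omics_block(y)) y else NULL
  xm <- as_feature_matrix(x)
  ym <- as_feature_matrix(y, "y")
  if (nrow(xm) != nrow(ym)) abort("Blocks must share the same samples.")
  if (!is.null(rownames(xm)) && !is.null(rownames(ym)) &&
      !identical(rownames(xm), rownames(ym))) {
    abort("Blocks must share sample identifiers in identical order.")
  }
  check_no_na(xm, "x")
  check_no_na(ym, "y")
  if (n_joint < 1) abort("`n_joint` must be at least 1.")
  if (n_joint > min(dim(xm), dim(ym))) abort("`n_joint` exceeds the block ranks.")
  scx <- scale_matrix(xm, scaling)
  scy <- scale_matrix(ym, scaling)
  core <- o2pls_core(scx$x, scy$x, n_joint, n_xorth, n_yorth)
  core$n_joint <- n_joint
  core$n_xorth <- n_xorth
  core$n_yorth <- n_yorth
  core$scaling <- scaling
  core$x_center <- scx$center
  core$x_scale <- scx$scale
  core$y_center <- scy$center
  core$y_scale <- scy$scale
  core$x_features <- colnames(xm) %||% paste0("x", seq_len(ncol(xm)))
  core$y_features <- colnames(ym) %||% paste0("y", seq_len(ncol(ym)))
  core$block_names <- c(
    if (!is.null(xb)) xb$name else "X",
    if (!is.null(yb)) yb$name else "Y"
  )
  class(core) <- "o2pls_model"
  core
}

#' @export
print.o2pls_model <- function(x, ...) {
  cat(sprintf(
    "<o2pls_model> %d joint, %d X-orthogonal, %d Y-orthogonal component(s)\n",
    x$n_joint, x$n_xorth, x$n_yorth
  ))
  v <- x$variance
  cat(sprintf(
    "  %s: joint %.3f, orthogonal %.3f, residual %.3f\n",
    v$block, v$joint, v$orthogonal, v$residual
  ), sep = "")
  invisible(x)
}

# Remove stored orthogonal variation from a new (scaled) block matrix.
strip_orth <- function(m, orth) {
  if (is.null(orth$w)) {
    return(m)
  }
  for (i in seq_len(ncol(orth$w))) {
    tt <- m %*% orth$w[, i, drop = FALSE]
    m <- m - tcrossprod(tt, orth$p[, i, drop = FALSE])
  }
  m
}

#' Predict one block from the other with an O2-PLS model
#'
#' @param object An `o2pls_model`.
#' @param newdata New data for the predictor block.
#' @param direction `"y_from_x"` or `"x_from_y"`.
#' @param ... Unused.
#' @return Predicted matrix for the other block, on its original scale.
#' @export
predict.o2pls_model <- function(object, newdata,
                                direction = c("y_from_x", "x_from_y"), ...) {
  direction <- match.arg(direction)
  m <- as_feature_matrix(newdata, "newdata")
  if (direction == "y_from_x") {
    ms <- sweep(sweep(m, 2, object$x_center, "-"), 2, object$x_scale, "/")
    ms <- strip_orth(ms, object$x_orth)
    pred_s <- ms %*% object$w %*% object$b_t %*% t(object$c)
    sweep(sweep(pred_s, 2, object$y_scale, "*"), 2, object$y_center, "+")
  } else {
    ms <- sweep(sweep(m, 2, object$y_center, "-"), 2, object$y_scale, "/")
    ms <- strip_orth(ms, object$y_orth)
    pred_s <- ms %*% object$c %*% object$b_u %*% t(object$w)
    sweep(sweep(pred_s, 2, object$x_scale, "*"), 2, object$x_center, "+")
  }
}

#' Cross-validated O2-PLS component selection
#'
#' Evaluates each `(n_joint, n_xorth, n_yorth)` grid point by k-fold
#' cross-validation of the symmetric prediction error: held-out `Y`
#' predicted from `X` plus held-out `X` predicted from `Y`, each normalized
#' by the held-out block's total sum of squares. Ties break toward the
#' smallest total component count, then the smallest joint count.
#'
#' @inheritParams fit_o2pls
#' @param n_joint,n_xorth,n_yorth Integer grids to search (defaults `1:3`,
#'   `0:2`, `0:2`).
#' @param folds Number of CV folds (default 7).
#' @param seed Seed for the fold assignment.
#' @return An object of class `o2pls_cv`: `best` (one-row tibble),
#'   `surface` (grid with CV errors) and `model` refitted on all data at
#'   the optimum.
#' @export
crossval_o2pls <- function(x, y, n_joint = 1:3, n_xorth = 0:2, n_yorth = 0:2,
                           folds = 7, seed = 1,
                           scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  xm <- as_feature_matrix(x)
  ym <- as_feature_matrix(y, "y")
  n <- nrow(xm)
  if (folds < 2) abort("`folds` must be at least 2.")
  assign <- make_folds(n, folds, seed)
  if (min(table(assign)) < 2) abort("Each fold needs at least 2 samples.")
  grid <- expand.grid(n_joint = n_joint, n_xorth = n_xorth, n_yorth = n_yorth)
  err <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    total <- 0
    for (f in seq_len(folds)) {
      test <- assign == f
      fit <- fit_o2pls(
        xm[!test, , drop = FALSE], ym[!test, , drop = FALSE],
        n_joint = grid$n_joint[gi], n_xorth = grid$n_xorth[gi],
        n_yorth = grid$n_yorth[gi], scaling = scaling
      )
      yhat <- predict(fit, xm[test, , drop = FALSE], direction = "y_from_x")
      xhat <- predict(fit, ym[test, , drop = FALSE], direction = "x_from_y")
      ss_y <- sum(sweep(ym[test, , drop = FALSE], 2, fit$y_center, "-")^2)
      ss_x <- sum(sweep(xm[test, , drop = FALSE], 2, fit$x_center, "-")^2)
      total <- total +
        sum((ym[test, , drop = FALSE] - yhat)^2) / max(ss_y, 1e-12) +
        sum((xm[test, , drop = FALSE] - xhat)^2) / max(ss_x, 1e-12)
    }
    err[gi] <- total / folds
  }
  surface <- as_tibble(grid)
  surface$cv_error <- err
  best <- surface |>
    dplyr::mutate(total = .data$n_joint + .data$n_xorth + .data$n_yorth) |>
    dplyr::filter(.data$cv_error <= min(.data$cv_error) + 1e-12) |>
    dplyr::arrange(.data$total, .data$n_joint) |>
    dplyr::slice(1) |>
    dplyr::select(-"total")
  model <- fit_o2pls(
    xm, ym,
    n_joint = best$n_joint, n_xorth = best$n_xorth,
    n_yorth = best$n_yorth, scaling = scaling
  )
  structure(
    list(best = best, surface = surface, model = model, folds = folds, seed = seed),
    class = "o2pls_cv"
  )
}

#' @export
print.o2pls_cv <- function(x, ...) {
  cat(sprintf(
    "<o2pls_cv> chosen: %d joint, %d X-orth, %d Y-orth (CV error %.4f, %d folds)\n",
    x$best$n_joint, x$best$n_xorth, x$best$n_yorth, x$best$cv_error, x$folds
  ))
  invisible(x)
}

#' Correlation-scaled joint loadings (pcorr / qcorr)
#'
#' Rescales the joint loadings as Pearson correlations between each original
#' variable and its block's joint score: `pcorr[j, k] = cor(x_j, t_k)` and
#' `qcorr[j, k] = cor(y_j, u_k)`. On the resulting correlation circle,
#' strongly positively associated variables project at ~0 degrees from each
#' other, negatively associated ones at ~180 degrees and uncorrelated ones
#' at ~90 degrees; distance from the origin measures the strength of the
#' variable-component relationship.
#'
#' @param model A fitted `o2pls_model`.
#' @param x,y The data the model was fitted on.
#' @return An object of class `correlation_loadings`: tibbles `pcorr` and
#'   `qcorr` (feature, block, one column per joint component).
#' @export
correlation_loadings <- function(model, x, y) {
  if (!inherits(model, "o2pls_model")) abort("`model` must be an o2pls_model.")
  xm <- as_feature_matrix(x)
  ym <- as_feature_matrix(y, "y")
  corr_block <- function(m, scores, features, block) {
    s <- col_sds(m)
    if (any(s == 0)) {
      warn("Zero-variance feature(s); correlation loadings set to 0.")
    }
    cc <- matrix(0, ncol(m), ncol(scores))
    ok <- s > 0
    cc[ok, ] <- cor(m[, ok, drop = FALSE], scores)
    colnames(cc) <- paste0("comp", seq_len(ncol(scores)))
    out <- as_tibble(cc)
    out <- dplyr::bind_cols(tibble(feature_id = features, block = block), out)
    out
  }
  structure(
    list(
      pcorr = corr_block(xm, model$t, model$x_features, model$block_names[1]),
      qcorr = corr_block(ym, model$u, model$y_features, model$block_names[2])
    ),
    class = "correlation_loadings"
  )
}

#' @export
print.correlation_loadings <- function(x, ...) {
  cat(sprintf(
    "<correlation_loadings> pcorr: %d features; qcorr: %d features\n",
    nrow(x$pcorr), nrow(x$qcorr)
  ))
  invisible(x)
}
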