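# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy an O-PLS model into a per-feature tibble
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, predictive `weight`, `loading` and
#'   `vip`.
#' @method tidy opls_model
#' @export
tidy.opls_model <- function(x, ...) {
  tibble(
    feature_id = x$feature_ids,
    weight = x$w,
    loading = x$p,
    vip = unname(vip(x))
  )
}

#' One-row model summary of an O-PLS fit
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_features`, `n_orth`, `R2Y`, `Q2Y`.
#' @method glance opls_model
#' @export
glance.opls_model <- function(x, ...) {
  tibble(
    n = x$n, n_features = length(x$w), n_orth = x$n_orth,
    R2Y = x$r2y, Q2Y = x$q2y
  )
}

#' Tidy a permutation test into its null draws
#'
#' @param x An `opls_permutation`.
#' @param ... Unused.
#' @return A long tibble with `statistic` (`"R2Y"`/`"Q2Y"`) and `value`.
#' @method tidy opls_permutation
#' @export
tidy.opls_permutation <- function(x, ...) {
  tibble(
    statistic = rep(c("R2Y", "Q2Y"), each = x$n_permutations),
    value = c(x$null_r2y, x$null_q2y)
  )
}

#' @rdname tidy.opls_permutation
#' @method glance opls_permutation
#' @export
glance.opls_permutation <- function(x, ...) {
  tibble(
    R2Y = x$r2y, Q2Y = x$q2y, p_R2Y = x$p_r2y, p_Q2Y = x$p_q2y,
    n_permutations = x$n_permutations
  )
}

#' Tidy an Mnet fit into a coefficient table
#'
#' @param x An `mnet_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and `penalized`.
#' @method tidy mnet_fit
#' @export
tidy.mnet_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept, penalized = FALSE),
    tibble(
      term = names(x$covariate_coef),
      estimate = unname(x$covariate_coef), penalized = FALSE
    ),
    tibble(term = names(x$beta), estimate = unname(x$beta), penalized = TRUE)
  )
}

#' @rdname tidy.mnet_fit
#' @method glance mnet_fit
#' @export
glance.mnet_fit <- function(x, ...) {
  tibble(
    lambda = x$lambda, alpha = x$alpha, gamma = x$gamma,
    n_nonzero = sum(x$beta != 0), iterations = x$iterations,
    converged = x$converged
  )
}

#' Tidy an Mnet cross-validation surface
#'
#' @param x An `mnet_cv`.
#' @param ... Unused.
#' @return The CV surface tibble (`lambda`, `alpha`, `gamma`, `mse`).
#' @method tidy mnet_cv
#' @export
tidy.mnet_cv <- function(x, ...) x$surface

#' @rdname tidy.mnet_cv
#' @method glance mnet_cv
#' @export
glance.mnet_cv <- function(x, ...) {
  dplyr::bind_cols(x$best, glance(x$fit)[c("n_nonzero", "converged")])
}

#' Tidy an O2-PLS model into long loadings
#'
#' @param x An `o2pls_model`.
#' @param ... Unused.
#' @return A tibble with `block`, `feature_id`, `component`, `loading`.
#' @method tidy o2pls_model
#' @export
tidy.o2pls_model <- function(x, ...) {
  per_block <- function(mat, features, block) {
    tibble(
      block = block,
      feature_id = rep(features, times = ncol(mat)),
      component = rep(seq_len(ncol(mat)), each = nrow(mat)),
      loading = as.vector(mat)
    )
  }
  dplyr::bind_rows(
    per_block(x$w, x$x_features, x$block_names[1]),
    per_block(x$c, x$y_features, x$block_names[2])
  )
}

#' @rdname tidy.o2pls_model
#' @method glance o2pls_model
#' @export
glance.o2pls_model <- function(x, ...) {
  out <- x$variance
  out$n_joint <- x$n_joint
  out$n_orth <- c(x$n_xorth, x$n_yorth)
  out
}

#' Tidy a discovery result into one association table
#'
#' @param x A `discovery_result`.
#' @param ... Unused.
#' @return The per-feature association tibble across blocks, with a `block`
#'   column.
#' @method tidy discovery_result
#' @export
tidy.discovery_result <- function(x, ...) {
  out <- dplyr::bind_rows(lapply(x$blocks, function(b) {
    if (!nrow(b$associations)) {
      return(NULL)
    }
    dplyr::bind_cols(tibble(block = b$block), b$associations)
  }))
  if (!nrow(out)) {
    out <- dplyr::bind_cols(tibble(block = character()), empty_association_table())
  }
  out
}

#' @rdname tidy.discovery_result
#' @method glance discovery_result
#' @export
glance.discovery_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$blocks, function(b) {
    if (is.null(b$model)) {
      return(tibble(
        block = b$block, n = NA_integer_, n_features = NA_integer_,
        n_orth = NA_integer_, R2Y = NA_real_, Q2Y = NA_real_,
        p_R2Y = NA_real_, p_Q2Y = NA_real_, n_permutations = NA_integer_,
        validated = b$validated, status = b$status
      ))
    }
    dplyr::bind_cols(b$model, tibble(validated = b$validated, status = b$status))
  }))
}

#' Tidy correlation-scaled loadings into long format
#'
#' @param x A `correlation_loadings` object.
#' @param ... Unused.
#' @return A long tibble with `block`, `feature_id`, `component`, `corr`.
#' @method tidy correlation_loadings
#' @export
tidy.correlation_loadings <- function(x, ...) {
  dplyr::bind_rows(x$pcorr, x$qcorr) |>
    tidyr::pivot_longer(
      dplyr::starts_with("comp"),
      names_to = "component", values_to = "corr",
      names_prefix = "comp", names_transform = as.integer
    )
}
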