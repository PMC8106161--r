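#' Per-sample alpha diversity
#'
#' Shannon entropy (natural log, via [vegan::diversity()]), observed species
#' and the Chao1 richness estimator. Chao1 defaults to the bias-corrected
#' form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, which is defined even without
#' doubletons; the classic `S_obs + F1^2 / (2 F2)` form matches textbook
#' examples and is available via `chao1`.
#'
#' @param block An [omics_block()] of kind `"counts"`.
#' @param chao1 `"bias_corrected"` (default) or `"classic"`.
#' @return A tibble with columns `sample_id`, `shannon`, `chao1`,
#'   `observed`.
#' @export
alpha_diversity <- function(block, chao1 = c("bias_corrected", "classic")) {
  chao1 <- match.arg(chao1)
  if (!is_omics_block(block)) block <- omics_block(block, kind = "counts")
  if (block$kind != "counts") abort("Alpha diversity requires a counts block.")
  x <- block$values
  if (any(rowSums(x) == 0)) abort("Alpha diversity undefined for empty samples.")
  shannon <- unname(vegan::diversity(x, index = "shannon"))
  observed <- as.integer(rowSums(x > 0))
  f1 <- rowSums(x == 1)
  f2 <- rowSums(x == 2)
  chao <- if (chao1 == "bias_corrected") {
    observed + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    ifelse(f2 > 0, observed + f1^2 / (2 * f2), observed + f1 * (f1 - 1) / 2)
  }
  tibble(
    sample_id = block$sample_ids,
    shannon = shannon, chao1 = unname(chao), observed = observed
  )
}

#' Between-sample beta diversity
#'
#' Canberra (unscaled sum of `|x - y| / (x + y)` over coordinates where the
#' pair is not both zero, as in [stats::dist()]), Bray-Curtis (via
#' [vegan::vegdist()]) or Euclidean distances. For Bray-Curtis, a pair
#' involving an all-zero sample is assigned distance 1 with a warning.
#'
#' @param block An [omics_block()].
#' @param metric One of `"canberra"`, `"bray_curtis"`, `"euclidean"`.
#' @return A [stats::dist] object labelled with the sample identifiers.
#' @export
beta_diversity <- function(block, metric = c("canberra", "bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  if (!is_omics_block(block)) abort("`block` must be an omics_block.")
  x <- block$values
  d <- switch(metric,
    canberra = dist(x, method = "canberra"),
    euclidean = dist(x, method = "euclidean"),
    bray_curtis = {
      zero <- rowSums(x) == 0
      d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
      if (any(zero)) {
        warn("All-zero sample(s); Bray-Curtis distances involving them set to 1.")
        m <- as.matrix(d)
        m[zero, ] <- 1
        m[, zero] <- 1
        diag(m) <- 0
        d <- as.dist(m)
      }
      d
    }
  )
  attr(d, "Labels") <- block$sample_ids
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by the
#' square root of their (positive) eigenvalues. Negative eigenvalues are
#' reported but excluded from the proportion-explained denominator; no
#' Lingoes/Cailliez correction is applied.
#'
#' @param d A [stats::dist] object or symmetric matrix of distances.
#' @param k Number of axes to return (`<= n - 1`).
#' @return An object of class `pcoa_ord` with `scores` (samples x axes),
#'   `eigenvalues` (all, sorted descending) and `prop_explained`.
#' @export
pcoa <- function(d, k = 2) {
  if (is.matrix(d)) {
    if (max(abs(d - t(d))) > 1e-12) abort("Distance matrix must be symmetric.")
    d <- as.dist(d)
  }
  n <- attr(d, "Size")
  if (k > n - 1) abort("`k` must be at most n - 1.")
  fit <- cmdscale(d, k = k, eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  scores <- fit$points
  if (ncol(scores) < k) {
    scores <- cbind(scores, matrix(0, n, k - ncol(scores)))
  }
  colnames(scores) <- paste0("Axis", seq_len(ncol(scores)))
  rownames(scores) <- attr(d, "Labels") %||% rownames(scores)
  structure(
    list(
      scores = scores,
      eigenvalues = sort(eig, decreasing = TRUE),
      prop_explained = pmax(eig[seq_len(k)], 0) / sum(pos)
    ),
    class = "pcoa_ord"
  )
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf(
    "<pcoa_ord> %d samples, %d axes (%.1f%%, %.1f%% explained)\n",
    nrow(x$scores), ncol(x$scores),
    100 * x$prop_explained[1], 100 * (x$prop_explained[2] %||% NA)
  ))
  invisible(x)
}

#' @rdname pcoa
#' @param x A `pcoa_ord` object.
#' @param ... Unused.
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) {
  out <- as_tibble(x$scores, rownames = "sample_id")
  out
}

# ---- PERMANOVA ------------------------------------------------------------

# One-way pseudo-F from a distance matrix (Anderson partitioning):
# SS_total = sum_{i<j} d_ij^2 / n; SS_within = sum over groups of the same
# quantity within each group; F = (SS_between / (a-1)) / (SS_within / (n-a)).
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  a <- length(lev)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  list(
    f = (ss_between / (a - 1)) / (ss_within / (n - a)),
    r2 = ss_between / ss_total
  )
}

# All distinct permutations of a label vector (multiset permutations of the
# group assignment). Used by the exact enumeration mode on small inputs.
multiset_permutations <- function(groups, limit = 2e5) {
  lev <- unique(groups)
  counts <- table(factor(groups, levels = lev))
  total <- factorial(length(groups)) / prod(factorial(counts))
  if (total > limit) {
    abort(sprintf("Exact enumeration would need %.0f relabelings; use method = 'montecarlo'.", total))
  }
  recurse <- function(remaining) {
    if (sum(remaining) == 0L) {
      return(list(integer(0)))
    }
    out <- list()
    for (i in seq_along(remaining)) {
      if (remaining[i] > 0L) {
        rem <- remaining
        rem[i] <- rem[i] - 1L
        for (tail in recurse(rem)) out[[length(out) + 1L]] <- c(i, tail)
      }
    }
    out
  }
  perms <- recurse(as.integer(counts))
  lapply(perms, function(idx) lev[idx])
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on a distance matrix. The Monte-Carlo p-value uses the
#' +1-smoothed estimator `(1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`
#' with seeded label shuffles; `method = "exact"` enumerates every distinct
#' relabeling instead (small n only) and reports the exact tail proportion
#' including the identity.
#'
#' @param d Distance matrix ([stats::dist] or symmetric matrix).
#' @param groups Group labels, one per sample (>= 2 groups).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param method `"montecarlo"` (default) or `"exact"`.
#' @return An object of class `permanova_result` with fields `pseudo_F`,
#'   `R2`, `p`, `n_permutations`, `method`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1,
                      method = c("montecarlo", "exact")) {
  method <- match.arg(method)
  m <- as.matrix(d)
  if (max(abs(m - t(m))) > 1e-12) abort("Distance matrix must be symmetric.")
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) abort("One group label per sample required.")
  if (length(unique(groups)) < 2) abort("PERMANOVA needs at least 2 groups.")
  if (n_permutations < 1) abort("`n_permutations` must be at least 1.")
  d2 <- m^2
  obs <- permanova_f(d2, groups)
  if (method == "exact") {
    perms <- multiset_permutations(groups)
    fs <- vapply(perms, function(g) permanova_f(d2, g)$f, numeric(1))
    p <- mean(fs >= obs$f - 1e-12)
    n_perm <- length(perms)
  } else {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(b) {
        permanova_f(d2, sample(groups))$f >= obs$f - 1e-12
      }, logical(1)))
    })
    p <- (1 + exceed) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(
    list(
      pseudo_F = obs$f, R2 = obs$r2, p = p,
      n_permutations = n_perm, method = method
    ),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (%s): pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$method, x$pseudo_F, x$R2, x$p, x$n_permutations
  ))
  invisible(x)
}

#' @rdname permanova
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @method glance permanova_result
#' @export
glance.permanova_result <- function(x, ...) {
  tibble(
    pseudo_F = x$pseudo_F, R2 = x$R2, p.value = x$p,
    n_permutations = x$n_permutations, method = x$method
  )
}
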