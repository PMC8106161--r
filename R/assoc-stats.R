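# Univariate confirmation statistics: covariate-adjusted partial Spearman
# correlation, BH adjustment, Mann-Kendall quartile trend, Wilcoxon rank-sum
# and hypergeometric over-representation.

# Build the covariate design: continuous columns are rank-transformed
# (average ranks); factors/characters/logicals enter as dummy columns
# (ranking a multi-level category is meaningless).
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) abort("Covariates must have one row per sample.")
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(rank(v), ncol = 1)
      colnames(m) <- nm
      m
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) {
        return(NULL)
      }
      m <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
      m
    }
  })
  do.call(cbind, c(cols[!vapply(cols, is.null, logical(1))], list(matrix(numeric(0), n, 0))))
}

# Residualize columns of `m` on [1, Z] via QR.
residualize <- function(m, z) {
  design <- cbind(1, z)
  qr_d <- qr(design)
  m - design %*% qr.coef(qr_d, m)
}

#' Covariate-adjusted partial Spearman correlation
#'
#' Ranks `x` and `y` (average ranks for ties), residualizes both on the
#' covariate design, and reports the Pearson correlation of the residuals —
#' the partial Spearman correlation (pSC) used for univariate confirmation
#' while adjusting for age, BMI, sex and country in the motivating study.
#' The p-value uses `t = rho * sqrt((n - 2 - k) / (1 - rho^2))` on
#' `n - 2 - k` degrees of freedom, where `k` is the number of covariate
#' columns after dummy encoding.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional data frame of covariates; numeric columns are
#'   rank-transformed, categorical columns are dummy-encoded.
#' @return A one-row tibble with `estimate` (rho), `statistic`, `df`,
#'   `p.value`.
#' @export
#' @examples
#' partial_spearman(c(1, 2, 3), c(3, 1, 2))
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  check_no_na(x, "x")
  check_no_na(y, "y")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: `x` or `y` is constant.")
  }
  z <- covariate_design(covariates, n)
  k <- ncol(z)
  if (n <= k + 2) abort("Need n > k + 2 samples for the partial correlation.")
  res <- residualize(cbind(rank(x), rank(y)), z)
  rho <- cor(res[, 1], res[, 2])
  rho <- min(max(rho, -1), 1)
  df <- n - 2 - k
  stat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  tibble(
    estimate = rho, statistic = stat, df = df,
    p.value = 2 * pt(-abs(stat), df = df)
  )
}

# Vectorized pSC of every column of `xm` against `y` given covariates.
psc_matrix <- function(xm, y, covariates = NULL) {
  n <- nrow(xm)
  z <- covariate_design(covariates, n)
  k <- ncol(z)
  ranks <- apply(xm, 2, rank)
  keep <- col_sds(ranks) > 0
  res_x <- residualize(ranks[, keep, drop = FALSE], z)
  res_y <- residualize(matrix(rank(y), ncol = 1), z)
  num <- as.vector(crossprod(res_x, res_y))
  den <- sqrt(colSums(res_x^2) * sum(res_y^2))
  rho <- rep(NA_real_, ncol(xm))
  rho[keep] <- pmin(pmax(num / den, -1), 1)
  df <- n - 2 - k
  stat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  tibble(
    feature_id = colnames(xm) %||% as.character(seq_len(ncol(xm))),
    psc_rho = rho,
    psc_p = 2 * pt(-abs(stat), df = df)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`min over j >= i of p_(j) * m / j`, clipped at
#' 1), returned in input order. Thin wrapper over
#' [stats::p.adjust()]`(method = "BH")` with range validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (pFDR), same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.05))
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Mann-Kendall trend test across ordered groups
#'
#' Monotone-trend test of values across ordered groups (here, response
#' quartiles): `S` sums `sign(g_j - g_i) * sign(v_j - v_i)` over all sample
#' pairs — Kendall's tau-b between group rank and value — with tie-corrected
#' variance, a continuity-corrected normal statistic and a two-sided
#' p-value.
#'
#' @param values Numeric vector.
#' @param groups Ordered group labels (ordered factor, numeric, or factor in
#'   level order), one per value; at least two distinct levels.
#' @return A one-row tibble with `S`, `tau`, `statistic` (z) and `p.value`.
#' @export
#' @examples
#' mann_kendall_trend(c(1, 2, 3, 4), c(1, 2, 3, 4))
mann_kendall_trend <- function(values, groups) {
  n <- length(values)
  if (length(groups) != n) abort("`values` and `groups` must have equal length.")
  g <- if (is.factor(groups)) as.integer(groups) else as.numeric(groups)
  if (length(unique(g)) < 2) abort("Trend test needs at least 2 distinct groups.")
  check_no_na(values, "values")

  sg <- sign(outer(g, g, "-"))
  sv <- sign(outer(values, values, "-"))
  up <- upper.tri(sg)
  s_stat <- sum(sg[up] * sv[up])

  tie_terms <- function(v, f) {
    t <- table(v)
    t <- t[t > 1]
    sum(f(as.numeric(t)))
  }
  d_pairs <- n * (n - 1) / 2
  tg <- tie_terms(g, function(t) t * (t - 1) / 2)
  tv <- tie_terms(values, function(t) t * (t - 1) / 2)
  tau <- s_stat / sqrt((d_pairs - tg) * (d_pairs - tv))

  v0 <- n * (n - 1) * (2 * n + 5)
  vg <- tie_terms(g, function(t) t * (t - 1) * (2 * t + 5))
  vv <- tie_terms(values, function(t) t * (t - 1) * (2 * t + 5))
  g3 <- tie_terms(g, function(t) t * (t - 1) * (t - 2))
  v3 <- tie_terms(values, function(t) t * (t - 1) * (t - 2))
  g2 <- 2 * tg
  v2 <- 2 * tv
  var_s <- (v0 - vg - vv) / 18 +
    g3 * v3 / (9 * n * (n - 1) * (n - 2)) +
    g2 * v2 / (2 * n * (n - 1))
  if (var_s <= 0) abort("Degenerate input: variance of S is zero.")
  z <- if (s_stat == 0) 0 else (s_stat - sign(s_stat)) / sqrt(var_s)
  tibble(
    S = as.integer(s_stat), tau = tau, statistic = z,
    p.value = 2 * pnorm(-abs(z))
  )
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two samples. In `"auto"` mode the exact
#' enumeration is used when the combined sample size is at most 20 and there
#' are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param a,b Numeric samples (both nonempty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return A one-row tibble with `U` (Mann-Whitney statistic for `a` vs
#'   `b`), `p.value` and `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) abort("Both samples must be nonempty.")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
    auto = (length(a) + length(b)) <= 20 && !ties,
    exact = TRUE,
    normal = FALSE
  )
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  p <- ht$p.value
  # fully tied inputs make the normal statistic 0/0; no evidence either way
  if (is.nan(p)) p <- 1
  tibble(
    U = unname(ht$statistic),
    p.value = p,
    method = if (exact && !ties) "exact" else "normal"
  )
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test `P(X >= k)` of the overlap between a
#' selected feature set and each predefined set, with Bonferroni (default)
#' or BH correction across the tested sets. Sets are intersected with the
#' universe before testing.
#'
#' @param selected Character vector of selected identifiers (must be a
#'   subset of `universe`).
#' @param gene_sets Named list of identifier vectors.
#' @param universe Character vector: all testable identifiers.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @return A tibble with `set_id`, `overlap`, `set_size`, `selected_size`,
#'   `universe_size`, `p.value`, `p_adjusted`, sorted by `p.value`.
#' @export
hypergeom_ora <- function(selected, gene_sets, universe,
                          correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  if (!length(universe)) abort("`universe` must be nonempty.")
  selected <- unique(selected)
  if (!all(selected %in% universe)) {
    abort("`selected` must be a subset of `universe`.")
  }
  n_sel <- length(selected)
  n_uni <- length(universe)
  rows <- purrr::imap(gene_sets, function(members, set_id) {
    members <- intersect(unique(members), universe)
    k <- length(intersect(members, selected))
    kk <- length(members)
    tibble(
      set_id = set_id, overlap = k, set_size = kk,
      selected_size = n_sel, universe_size = n_uni,
      p.value = phyper(k - 1, kk, n_uni - kk, n_sel, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (correction == "bonferroni") {
    pmin(1, out$p.value * nrow(out))
  } else {
    bh_adjust(out$p.value)
  }
  dplyr::arrange(out, .data$p.value)
}

#' Read gene sets in GMT format
#'
#' Each line is tab-separated: set name, description, then member
#' identifiers.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}
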