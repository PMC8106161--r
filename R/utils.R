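# Internal helpers shared across modules.

# Deterministic sub-seed derivation: a master seed plus a component label maps
# to a 31-bit seed, so adding a block to a dataset never perturbs the draws of
# blocks generated before it.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 1000003
  }
  as.integer((abs(seed) + h * 1009 + 7) %% (.Machine$integer.max - 1L))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Column sds without apply() overhead (denominator n - 1).
col_sds <- function(x) {
  n <- nrow(x)
  cm <- colMeans(x)
  v <- (colSums(x^2) - n * cm^2) / (n - 1)
  sqrt(pmax(v, 0))
}

# Center/scale a matrix per the chemometric conventions used throughout.
scale_matrix <- function(x, scaling = c("uv", "pareto", "none"),
                         center = NULL, scale = NULL) {
  scaling <- match.arg(scaling)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    s <- col_sds(x)
    scale <- switch(scaling, uv = s, pareto = sqrt(s), none = rep(1, ncol(x)))
    scale[scale == 0] <- 1
  }
  list(
    x = sweep(sweep(x, 2, center, "-"), 2, scale, "/"),
    center = center, scale = scale
  )
}

as_feature_matrix <- function(x, arg = "x") {
  if (is_omics_block(x)) {
    return(x$values)
  }
  if (is.data.frame(x)) {
    id_col <- intersect(c("sample_id", "feature_id"), names(x))
    if (length(id_col)) {
      ids <- x[[id_col[1]]]
      x <- x[setdiff(names(x), id_col)]
      m <- as.matrix(x)
      rownames(m) <- ids
      return(m)
    }
    return(as.matrix(x))
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) abort(sprintf("`%s` must be a numeric matrix or data frame.", arg))
  x
}

check_no_na <- function(x, arg) {
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values.", arg))
  }
  invisible(x)
}

# k-fold assignment: stratified-by-order base pattern, shuffled under `seed`.
make_folds <- function(n, k, seed) {
  if (k < 2) abort("`folds` must be at least 2.")
  base <- rep_len(seq_len(k), n)
  with_seed(seed, sample(base))
}
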