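#' Construct an omics block
#'
#' An omics block is the package's container for one sample-by-feature table:
#' taxa counts, metabolite intensities or transcript levels. Rows are samples,
#' columns are features; both carry identifiers.
#'
#' @param values Numeric samples-by-features matrix (or data frame with an
#'   optional `sample_id` column). For `kind = "counts"` entries must be
#'   nonnegative integers.
#' @param kind `"counts"` for sequencing-derived count tables, `"intensity"`
#'   for positive continuous measurements (and for closed relative
#'   abundances).
#' @param name Label for the block (used in result tables).
#'
#' @return An object of class `omics_block` with fields `name`, `kind`,
#'   `sample_ids`, `feature_ids` and `values`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 10), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), paste0("taxon", 1:4)))
#' omics_block(m, kind = "counts", name = "taxa")
omics_block <- function(values, kind = c("counts", "intensity"), name = "block") {
  kind <- match.arg(kind)
  values <- as_feature_matrix(values, "values")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s_f%04d", name, seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) abort("Duplicate sample identifiers.")
  if (anyDuplicated(colnames(values))) abort("Duplicate feature identifiers.")
  check_no_na(values, "values")
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      abort("A counts block must contain nonnegative integers.")
    }
    storage.mode(values) <- "integer"
  }
  structure(
    list(
      name = name, kind = kind,
      sample_ids = rownames(values), feature_ids = colnames(values),
      values = values
    ),
    class = "omics_block"
  )
}

is_omics_block <- function(x) inherits(x, "omics_block")

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf(
    "<omics_block> '%s' (%s): %d samples x %d features\n",
    x$name, x$kind, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

#' @export
as.matrix.omics_block <- function(x, ...) x$values

#' Tidy an omics block into long format
#'
#' @param x An [omics_block()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `feature_id`, `value`.
#' @method tidy omics_block
#' @export
tidy.omics_block <- function(x, ...) {
  tibble(
    sample_id = rep(x$sample_ids, times = length(x$feature_ids)),
    feature_id = rep(x$feature_ids, each = length(x$sample_ids)),
    value = as.vector(x$values)
  )
}

# Rebuild a block around a transformed value matrix, preserving metadata.
replace_values <- function(block, values, kind = block$kind) {
  structure(
    list(
      name = block$name, kind = kind,
      sample_ids = rownames(values), feature_ids = colnames(values),
      values = values
    ),
    class = "omics_block"
  )
}
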