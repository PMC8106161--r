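# TSV + YAML manifest serialization for synthetic datasets. Feature tables
# are written features-by-samples (first column `feature_id`, header row of
# sample IDs) with doubles formatted at full precision (%.17g) so that
# write -> read round-trips exactly.

format_full <- function(x) {
  if (is.integer(x) || all(x == round(x))) {
    format(x, scientific = FALSE, trim = TRUE)
  } else {
    sprintf("%.17g", x)
  }
}

write_block_tsv <- function(block, path) {
  m <- t(block$values) # features x samples
  df <- as.data.frame(apply(m, 2, format_full), stringsAsFactors = FALSE,
                      optional = TRUE)
  if (nrow(m) == 1) df <- as.data.frame(as.list(setNames(
    vapply(seq_len(ncol(m)), function(j) format_full(m[1, j]), character(1)),
    colnames(m)
  )))
  colnames(df) <- colnames(m)
  df <- cbind(feature_id = rownames(m), df)
  readr::write_tsv(as_tibble(df), path)
}

#' Read an omics block from TSV
#'
#' @param path TSV written by [write_dataset()] (or any table in the same
#'   dialect).
#' @param kind Block kind.
#' @param name Block label (defaults to the file name).
#' @param orientation `"features_by_samples"` (the package's output dialect)
#'   or `"samples_by_features"`; never guessed silently.
#' @return An [omics_block()].
#' @export
read_omics_block <- function(path, kind = c("counts", "intensity"),
                             name = tools::file_path_sans_ext(basename(path)),
                             orientation = c("features_by_samples", "samples_by_features")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[-1])
  rownames(m) <- ids
  if (orientation == "features_by_samples") m <- t(m)
  omics_block(m, kind = kind, name = name)
}

#' Write a synthetic dataset to a directory
#'
#' One TSV per block (features by samples), a metadata TSV, a truth TSV and
#' a YAML manifest recording the seed, the orientation and per-block kinds.
#'
#' @param ds A `synthetic_dataset` from [simulate_dataset()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, the manifest as a list.
#' @export
write_dataset <- function(ds, directory) {
  if (!inherits(ds, "synthetic_dataset")) abort("`ds` must be a synthetic_dataset.")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = ds$seed,
    orientation = "features_by_samples",
    response = attr(ds$cohort, "response_name") %||% "ferritin",
    metadata = "metadata.tsv",
    truth = "truth.tsv",
    blocks = list()
  )
  for (b in ds$blocks) {
    file <- paste0("block_", b$name, ".tsv")
    write_block_tsv(b, file.path(directory, file))
    manifest$blocks[[b$name]] <- list(file = file, kind = b$kind)
  }
  meta <- ds$cohort
  num <- vapply(meta, is.double, logical(1))
  meta[num] <- lapply(meta[num], format_full)
  readr::write_tsv(meta, file.path(directory, "metadata.tsv"))
  readr::write_tsv(ds$truth, file.path(directory, "truth.tsv"))
  yaml::write_yaml(manifest, file.path(directory, "manifest.yaml"))
  invisible(manifest)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param directory Directory containing `manifest.yaml`.
#' @return A `synthetic_dataset` (cohort, blocks, truth).
#' @export
read_dataset <- function(directory) {
  manifest <- yaml::read_yaml(file.path(directory, "manifest.yaml"))
  cohort <- as_tibble(utils::read.delim(
    file.path(directory, manifest$metadata),
    check.names = FALSE, stringsAsFactors = FALSE
  ))
  attr(cohort, "response_name") <- manifest$response
  class(cohort) <- c("cohort_table", class(cohort))
  blocks <- list()
  for (nm in names(manifest$blocks)) {
    entry <- manifest$blocks[[nm]]
    blocks[[nm]] <- read_omics_block(
      file.path(directory, entry$file),
      kind = entry$kind, name = nm,
      orientation = manifest$orientation
    )
  }
  truth_path <- file.path(directory, manifest$truth)
  truth <- if (file.exists(truth_path)) {
    as_tibble(utils::read.delim(truth_path, check.names = FALSE, stringsAsFactors = FALSE))
  } else {
    NULL
  }
  structure(
    list(cohort = cohort, blocks = blocks, truth = truth, seed = manifest$seed),
    class = "synthetic_dataset"
  )
}
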