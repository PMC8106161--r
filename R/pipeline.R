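# End-to-end orchestration of the discovery -> validation -> confirmation
# workflow: preprocess each block, fit and permutation-validate an O-PLS
# model of the response, select features by the VIP/pFDR rule, confirm each
# selected feature by covariate-adjusted partial Spearman correlation; plus
# Mnet discovery, O2-PLS integration, Ward clustering and reporting.

#' Pipeline configuration
#'
#' Collects every tunable stage parameter with the workflow's defaults.
#'
#' @param response Response column name in the cohort/metadata table.
#' @param covariates Covariate column names used for partial-Spearman
#'   adjustment (and, dummy-encoded, as unpenalized Mnet covariates).
#' @param filter_abundance,filter_prevalence Feature-filter thresholds
#'   applied to count blocks. The default is a detection-level rule
#'   (relative abundance > 0.001 in at least 20\% of samples); the
#'   published verbatim rule (0.2/0.2) is available by setting both to 0.2.
#' @param pseudocount Offset for the log10 transform; `NULL` uses half the
#'   smallest nonzero value of each block.
#' @param n_orth Orthogonal components for the O-PLS models (or `"auto"`).
#' @param n_permutations Permutations for model validation (default 1000).
#' @param permutation_cv Q2 cross-validation inside the permutation test:
#'   `"loo"` or an integer fold count.
#' @param gate_alpha Permutation p(Q2Y) threshold a model must pass before
#'   feature selection proceeds (default 0.05).
#' @param fdr_primary,fdr_relaxed,vip_cut Selection rule thresholds.
#' @param psc_alpha Partial-Spearman confirmation threshold on the raw p
#'   (default 0.05).
#' @param mnet_alpha,mnet_gamma,mnet_nlambda,mnet_folds Mnet tuning grids.
#' @param o2pls_joint,o2pls_xorth,o2pls_yorth,o2pls_folds O2-PLS CV grids.
#' @param seed Master seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(response = "ferritin",
                            covariates = c("age", "bmi", "sex", "country"),
                            filter_abundance = 0.001,
                            filter_prevalence = 0.2,
                            pseudocount = NULL,
                            n_orth = 1,
                            n_permutations = 1000,
                            permutation_cv = "loo",
                            gate_alpha = 0.05,
                            fdr_primary = 0.05,
                            fdr_relaxed = 0.10,
                            vip_cut = 1.0,
                            psc_alpha = 0.05,
                            mnet_alpha = c(0.1, 0.5, 0.9),
                            mnet_gamma = c(2.5, 3, 8),
                            mnet_nlambda = 50,
                            mnet_folds = 10,
                            o2pls_joint = 1:2,
                            o2pls_xorth = 0:1,
                            o2pls_yorth = 0:1,
                            o2pls_folds = 7,
                            seed = 1) {
  stopifnot(
    fdr_primary > 0, fdr_primary < 1, fdr_relaxed > 0, fdr_relaxed < 1,
    psc_alpha > 0, psc_alpha < 1, gate_alpha > 0, gate_alpha < 1
  )
  structure(as.list(environment()), class = "pipeline_config")
}

# Shared preparation: counts -> relative abundance -> filter -> log10;
# intensities -> log10.
prepare_block <- function(block, config) {
  if (block$kind == "counts") {
    block <- filter_features(
      block,
      abundance_threshold = config$filter_abundance,
      prevalence_threshold = config$filter_prevalence
    )
    if (ncol(block$values) == 0) return(block)
    block <- relative_abundance(block)
  }
  pc <- config$pseudocount
  if (is.null(pc)) {
    pos <- block$values[block$values > 0]
    pc <- if (any(block$values == 0)) min(pos) / 2 else 0
  }
  log10_transform(block, pseudocount = pc)
}

#' Run the O-PLS discovery stage on every block
#'
#' Per block: preprocess, fit an O-PLS model of the response, validate it by
#' permutation testing, and — only if the permutation p-value for Q2Y passes
#' the gate — select features by the VIP/pFDR rule and confirm each selected
#' feature by covariate-adjusted partial Spearman correlation. A gated-out
#' block yields an explicit "model not valid" record, not an error.
#'
#' @param dataset A `synthetic_dataset`, or a named list of
#'   [omics_block()]s together with `metadata`.
#' @param config A [pipeline_config()].
#' @param metadata Cohort/metadata tibble when `dataset` is a plain block
#'   list.
#' @return An object of class `discovery_result`: per-block entries holding
#'   `model` stats, `validated`, and the association table with `selected`,
#'   `psc_rho`, `psc_p` and `confirmed` flags.
#' @export
run_discovery <- function(dataset, config = pipeline_config(), metadata = NULL) {
  parts <- resolve_dataset(dataset, metadata)
  y <- parts$metadata[[config$response]]
  if (is.null(y)) abort(sprintf("Response column '%s' not found.", config$response))
  covs <- parts$metadata[intersect(config$covariates, names(parts$metadata))]
  results <- list()
  for (nm in names(parts$blocks)) {
    block <- prepare_block(parts$blocks[[nm]], config)
    if (ncol(block$values) < 2) {
      results[[nm]] <- list(
        block = nm, validated = FALSE,
        status = "too few features after filtering",
        model = NULL, associations = empty_association_table()
      )
      next
    }
    fit <- fit_opls(block$values, y,
      n_orth = config$n_orth, q2 = FALSE
    )
    perm <- permutation_test(
      block$values, y,
      n_orth = fit$n_orth,
      n_permutations = config$n_permutations,
      seed = derive_seed(config$seed, paste0("perm:", nm)),
      cv = config$permutation_cv
    )
    fit$q2y <- perm$q2y
    validated <- perm$p_q2y < config$gate_alpha
    if (!validated) {
      results[[nm]] <- list(
        block = nm, validated = FALSE, status = "model not valid",
        model = model_stats(nm, fit, perm),
        associations = empty_association_table()
      )
      next
    }
    assoc <- select_features(
      block$values, y, fit,
      fdr_primary = config$fdr_primary,
      fdr_relaxed = config$fdr_relaxed,
      vip_cut = config$vip_cut
    )
    psc <- psc_matrix(block$values, y, covs)
    assoc <- dplyr::left_join(assoc, psc, by = "feature_id")
    assoc$confirmed <- assoc$selected & !is.na(assoc$psc_p) &
      assoc$psc_p < config$psc_alpha
    results[[nm]] <- list(
      block = nm, validated = TRUE, status = "ok",
      model = model_stats(nm, fit, perm),
      associations = assoc
    )
  }
  structure(
    list(blocks = results, config = config, response = config$response),
    class = "discovery_result"
  )
}

model_stats <- function(nm, fit, perm) {
  tibble(
    block = nm, n = fit$n, n_features = length(fit$w), n_orth = fit$n_orth,
    R2Y = fit$r2y, Q2Y = fit$q2y,
    p_R2Y = perm$p_r2y, p_Q2Y = perm$p_q2y,
    n_permutations = perm$n_permutations
  )
}

empty_association_table <- function() {
  tibble(
    feature_id = character(), loading_corr = numeric(), vip = numeric(),
    p.value = numeric(), p_fdr = numeric(), selected = logical(),
    psc_rho = numeric(), psc_p = numeric(), confirmed = logical()
  )
}

resolve_dataset <- function(dataset, metadata) {
  if (inherits(dataset, "synthetic_dataset")) {
    list(blocks = dataset$blocks, metadata = dataset$cohort)
  } else {
    if (is.null(metadata)) abort("Provide `metadata` with a plain block list.")
    if (is_omics_block(dataset)) dataset <- setNames(list(dataset), dataset$name)
    list(blocks = dataset, metadata = metadata)
  }
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("<discovery_result> %d block(s)\n", length(x$blocks)))
  for (b in x$blocks) {
    if (!is.null(b$model)) {
      cat(sprintf(
        "  %s: %s | R2Y = %.3f, Q2Y = %.3f, p(Q2Y) = %.4g | %d selected, %d confirmed\n",
        b$block, b$status, b$model$R2Y, b$model$Q2Y, b$model$p_Q2Y,
        sum(b$associations$selected), sum(b$associations$confirmed)
      ))
    } else {
      cat(sprintf("  %s: %s\n", b$block, b$status))
    }
  }
  invisible(x)
}

#' Run the Mnet discovery stage on one block
#'
#' CV-tuned Mnet regression of the response on the preprocessed block with
#' the configured covariates entered unpenalized; optionally summarizes the
#' overlap with an O-PLS discovery result.
#'
#' @inheritParams run_discovery
#' @param block_name Which block of the dataset to model (default: first).
#' @param opls_result Optional `discovery_result` for overlap reporting.
#' @return An object of class `mnet_discovery`: the `mnet_cv` object, a
#'   coefficient tibble and (optionally) the overlap summary.
#' @export
run_mnet_discovery <- function(dataset, config = pipeline_config(),
                               metadata = NULL, block_name = NULL,
                               opls_result = NULL) {
  parts <- resolve_dataset(dataset, metadata)
  block_name <- block_name %||% names(parts$blocks)[1]
  y <- parts$metadata[[config$response]]
  covs <- parts$metadata[intersect(config$covariates, names(parts$metadata))]
  block <- prepare_block(parts$blocks[[block_name]], config)
  cv <- cv_mnet(
    block$values, y,
    covariates = if (ncol(covs)) covs else NULL,
    alpha = config$mnet_alpha, gamma = config$mnet_gamma,
    nlambda = config$mnet_nlambda, n_folds = config$mnet_folds,
    seed = derive_seed(config$seed, paste0("mnet:", block_name))
  )
  coef_tab <- tibble(
    feature_id = names(cv$fit$beta),
    estimate = unname(cv$fit$beta),
    nonzero = cv$fit$beta != 0
  )
  overlap <- NULL
  if (!is.null(opls_result) && block_name %in% names(opls_result$blocks)) {
    assoc <- opls_result$blocks[[block_name]]$associations
    sel_opls <- assoc$feature_id[assoc$confirmed]
    sel_mnet <- coef_tab$feature_id[coef_tab$nonzero]
    overlap <- tibble(
      block = block_name,
      n_opls_confirmed = length(sel_opls),
      n_mnet_nonzero = length(sel_mnet),
      n_overlap = length(intersect(sel_opls, sel_mnet))
    )
  }
  structure(
    list(
      block = block_name, cv = cv, coefficients = coef_tab,
      overlap = overlap, config = config
    ),
    class = "mnet_discovery"
  )
}

#' @export
print.mnet_discovery <- function(x, ...) {
  cat(sprintf("<mnet_discovery> block '%s'\n", x$block))
  print(x$cv)
  invisible(x)
}

#' Run the O2-PLS integration stage on two feature subsets
#'
#' Restricts two blocks to the supplied (typically response-associated)
#' feature sets, selects O2-PLS components by k-fold cross-validation, and
#' computes correlation-scaled loadings plus the all-pairs partial-Spearman
#' heatmap table with a display mask at raw `p < 0.05` and a highlight mask
#' at `pFDR < 0.05` (highlighted is always a subset of displayed).
#'
#' @inheritParams run_discovery
#' @param block_x,block_y Names of the two blocks.
#' @param features_x,features_y Nonempty feature-id subsets.
#' @return An object of class `integration_result`: `cv` (o2pls_cv),
#'   `loadings` (correlation_loadings) and `heatmap` (long tibble with
#'   `rho`, `p.value`, `p_fdr`, `displayed`, `highlighted`).
#' @export
run_integration <- function(dataset, block_x, block_y, features_x, features_y,
                            config = pipeline_config(), metadata = NULL) {
  if (!length(features_x) || !length(features_y)) {
    abort("Feature subsets must be nonempty.")
  }
  parts <- resolve_dataset(dataset, metadata)
  covs <- parts$metadata[intersect(config$covariates, names(parts$metadata))]
  bx <- prepare_block(parts$blocks[[block_x]], config)
  by <- prepare_block(parts$blocks[[block_y]], config)
  xm <- bx$values[, intersect(features_x, colnames(bx$values)), drop = FALSE]
  ym <- by$values[, intersect(features_y, colnames(by$values)), drop = FALSE]
  if (!ncol(xm) || !ncol(ym)) abort("Feature subsets not found in the blocks.")
  cv <- crossval_o2pls(
    xm, ym,
    n_joint = config$o2pls_joint, n_xorth = config$o2pls_xorth,
    n_yorth = config$o2pls_yorth, folds = config$o2pls_folds,
    seed = derive_seed(config$seed, "o2pls")
  )
  loadings <- correlation_loadings(cv$model, xm, ym)
  pairs <- tidyr::expand_grid(
    feature_x = colnames(xm), feature_y = colnames(ym)
  )
  stats <- purrr::map2(pairs$feature_x, pairs$feature_y, function(fx, fy) {
    partial_spearman(xm[, fx], ym[, fy], if (ncol(covs)) covs else NULL)
  })
  pairs$rho <- vapply(stats, function(s) s$estimate, numeric(1))
  pairs$p.value <- vapply(stats, function(s) s$p.value, numeric(1))
  pairs$p_fdr <- bh_adjust(pairs$p.value)
  pairs$displayed <- pairs$p.value < 0.05
  pairs$highlighted <- pairs$p_fdr < 0.05
  structure(
    list(
      block_x = block_x, block_y = block_y,
      cv = cv, loadings = loadings, heatmap = pairs, config = config
    ),
    class = "integration_result"
  )
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(
    "<integration_result> %s x %s: %d pairs, %d displayed, %d highlighted\n",
    x$block_x, x$block_y, nrow(x$heatmap),
    sum(x$heatmap$displayed), sum(x$heatmap$highlighted)
  ))
  print(x$cv)
  invisible(x)
}

#' Hierarchical cluster ordering (Ward on Euclidean distances)
#'
#' Agglomerative clustering of a z-scored samples-by-features matrix with
#' the Ward.D2 criterion on Euclidean distances, for both samples (rows) and
#' features (columns); returns trees, merge heights and leaf orders for
#' heatmap layout.
#'
#' @param m Numeric matrix (typically the output of [zscore()]).
#' @return An object of class `cluster_order`: `sample_tree`,
#'   `feature_tree` ([stats::hclust] objects), `sample_order`,
#'   `feature_order`.
#' @export
hca_order <- function(m) {
  if (is_omics_block(m)) m <- m$values
  m <- as.matrix(m)
  if (nrow(m) < 2) abort("Clustering needs at least 2 rows.")
  check_no_na(m, "m")
  sample_tree <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  feature_tree <- if (ncol(m) >= 2) {
    hclust(dist(t(m), method = "euclidean"), method = "ward.D2")
  } else {
    NULL
  }
  structure(
    list(
      sample_tree = sample_tree, feature_tree = feature_tree,
      sample_order = sample_tree$order,
      feature_order = if (is.null(feature_tree)) seq_len(ncol(m)) else feature_tree$order
    ),
    class = "cluster_order"
  )
}

#' Write a structured report of pipeline stage outputs
#'
#' Writes per-stage TSVs (floats at 12 significant digits), a YAML run
#' manifest (configuration, seed, package version, file hashes) and a
#' plain-text summary of validated models and selection counts. When a
#' truth table is supplied, recovery metrics (sensitivity and false
#' discovery among confirmed features) are included; with no truth the
#' recovery section is omitted. Missing stages are noted, never fatal.
#'
#' @param directory Output directory.
#' @param discovery Optional `discovery_result`.
#' @param mnet Optional `mnet_discovery`.
#' @param integration Optional `integration_result`.
#' @param truth Optional ground-truth tibble (from a `synthetic_dataset`).
#' @return Invisibly, the manifest list.
#' @export
make_report <- function(directory, discovery = NULL, mnet = NULL,
                        integration = NULL, truth = NULL) {
  if (is.null(discovery) && is.null(mnet) && is.null(integration)) {
    abort("At least one completed stage is required.")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_stage <- function(df, file) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
    readr::write_tsv(df, file.path(directory, file))
    file
  }
  files <- character(0)
  lines <- c("Pipeline report", "===============")
  if (!is.null(discovery)) {
    files <- c(files, write_stage(glance(discovery), "discovery_models.tsv"))
    files <- c(files, write_stage(tidy(discovery), "discovery_associations.tsv"))
    g <- glance(discovery)
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, sprintf(
        "block %s: R2Y = %.4f, Q2Y = %.4f, p(Q2Y) = %.4g, validated = %s",
        g$block[i], g$R2Y[i], g$Q2Y[i], g$p_Q2Y[i], g$validated[i]
      ))
    }
    assoc <- tidy(discovery)
    lines <- c(lines, sprintf(
      "selected features: %d; confirmed by pSC: %d",
      sum(assoc$selected, na.rm = TRUE), sum(assoc$confirmed, na.rm = TRUE)
    ))
    if (!is.null(truth) && nrow(truth)) {
      planted <- truth$feature_id[truth$type == "response_effect"]
      confirmed <- assoc$feature_id[assoc$confirmed]
      sens <- if (length(planted)) {
        length(intersect(confirmed, planted)) / length(planted)
      } else {
        NA_real_
      }
      fdr <- if (length(confirmed)) {
        length(setdiff(confirmed, planted)) / length(confirmed)
      } else {
        0
      }
      lines <- c(lines, sprintf(
        "recovery vs truth: sensitivity = %.3f, false discovery = %.3f",
        sens, fdr
      ))
      files <- c(files, write_stage(
        tibble(sensitivity = sens, false_discovery = fdr), "recovery.tsv"
      ))
    }
  } else {
    lines <- c(lines, "discovery stage: not run")
  }
  if (!is.null(mnet)) {
    files <- c(files, write_stage(mnet$coefficients, "mnet_coefficients.tsv"))
    lines <- c(lines, sprintf(
      "mnet block %s: %d nonzero coefficients (lambda = %.4g, alpha = %.2f, gamma = %.3g)",
      mnet$block, sum(mnet$coefficients$nonzero),
      mnet$cv$best$lambda, mnet$cv$best$alpha, mnet$cv$best$gamma
    ))
    if (!is.null(mnet$overlap)) {
      files <- c(files, write_stage(mnet$overlap, "mnet_opls_overlap.tsv"))
    }
  } else {
    lines <- c(lines, "mnet stage: not run")
  }
  if (!is.null(integration)) {
    files <- c(files, write_stage(integration$heatmap, "integration_heatmap.tsv"))
    files <- c(files, write_stage(
      dplyr::bind_rows(integration$loadings$pcorr, integration$loadings$qcorr),
      "integration_correlation_loadings.tsv"
    ))
    lines <- c(lines, sprintf(
      "integration %s x %s: %d joint component(s), %d highlighted pair(s)",
      integration$block_x, integration$block_y,
      integration$cv$best$n_joint, sum(integration$heatmap$highlighted)
    ))
  } else {
    lines <- c(lines, "integration stage: not run")
  }
  writeLines(lines, file.path(directory, "summary.txt"))
  cfg <- (discovery %||% mnet %||% integration)$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("ferromics")),
    seed = cfg$seed,
    config = unclass(cfg),
    files = as.list(setNames(
      unname(tools::md5sum(file.path(directory, files))), files
    ))
  )
  yaml::write_yaml(manifest, file.path(directory, "manifest.yaml"))
  invisible(manifest)
}
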