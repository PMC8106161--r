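# Seeded generator for coupled phenotype/omics cohorts. The generator
# emulates the structure the discovery pipeline assumes: a skewed positive
# response (log-normal, like serum ferritin), covariates tied to the
# response through a Gaussian copula, overdispersed compositional taxa
# counts (Dirichlet-multinomial), log-normal intensity blocks, planted
# response effects on the log-abundance scale, and cross-block links
# realized through shared latent factors.

#' Specify a synthetic cohort
#'
#' @param n_samples Number of samples (>= 4).
#' @param response_name Name of the response column (default `"ferritin"`).
#' @param response_log_mean,response_log_sd Log-normal parameters of the
#'   response (`response_log_sd = 0` yields a constant response).
#' @param covariates List of covariate definitions, each a list with
#'   `name`, `kind` (`"continuous"`, `"binary"` or `"categorical"`) and
#'   distribution parameters: continuous `mean`/`sd` (optionally
#'   `dist = "lognormal"` with `meanlog`/`sdlog`), binary `prob`, categorical
#'   `levels`/`probs`.
#' @param confounding Named numeric vector of latent (copula) correlations
#'   in `[-1, 1]` between each covariate and the log response.
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 100,
                        response_name = "ferritin",
                        response_log_mean = log(80),
                        response_log_sd = 0.8,
                        covariates = default_covariates(),
                        confounding = c(age = 0.2, bmi = 0.15, hs_crp = 0.3),
                        seed = 1) {
  if (n_samples < 4) abort("`n_samples` must be at least 4.")
  if (response_log_sd < 0) abort("`response_log_sd` must be nonnegative.")
  cov_names <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(cov_names)) abort("Duplicate covariate names.")
  if (length(confounding)) {
    if (is.null(names(confounding)) || !all(names(confounding) %in% cov_names)) {
      abort("`confounding` must be named after covariates.")
    }
    if (any(abs(confounding) > 1)) abort("Confounding correlations must lie in [-1, 1].")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), response_name = response_name,
      response_log_mean = response_log_mean, response_log_sd = response_log_sd,
      covariates = covariates, confounding = confounding, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Default covariate definitions
#'
#' Age and BMI as continuous normals, sex as a balanced binary, country as a
#' two-level category, and hs-CRP as a log-normal — the covariate set the
#' confirmation statistics adjust for.
#'
#' @return List of covariate definitions for [cohort_spec()].
#' @export
default_covariates <- function() {
  list(
    list(name = "age", kind = "continuous", mean = 43, sd = 9),
    list(name = "bmi", kind = "continuous", mean = 30, sd = 5),
    list(name = "sex", kind = "binary", prob = 0.5),
    list(
      name = "country", kind = "categorical",
      levels = c("IT", "ES"), probs = c(0.5, 0.5)
    ),
    list(name = "hs_crp", kind = "continuous", dist = "lognormal", meanlog = 0.5, sdlog = 0.8)
  )
}

#' Generate a synthetic cohort table
#'
#' Draws the response log-normal and the covariates through a Gaussian
#' copula: each covariate's latent normal is mixed with the response's
#' latent normal at the requested correlation, then pushed through the
#' covariate's marginal. Continuous normal covariates therefore reproduce
#' the requested Pearson correlation with the log response exactly (up to
#' Monte-Carlo error); discretized (binary/categorical) covariates realize
#' an attenuated observed correlation, as discretization always does.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed override (defaults to the spec's seed).
#' @return A tibble (`cohort_table`) with `sample_id`, the response column,
#'   the covariates, and `response_quartile`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  n <- spec$n_samples
  with_seed(derive_seed(seed, "cohort"), {
    z0 <- rnorm(n)
    response <- exp(spec$response_log_mean + spec$response_log_sd * z0)
    out <- tibble(sample_id = sprintf("S%04d", seq_len(n)))
    out[[spec$response_name]] <- response
    for (cv in spec$covariates) {
      r <- unname(spec$confounding[cv$name])
      if (is.na(r) || !length(r)) r <- 0
      zj <- r * z0 + sqrt(1 - r^2) * rnorm(n)
      out[[cv$name]] <- switch(cv$kind,
        continuous = if (identical(cv$dist, "lognormal")) {
          exp(cv$meanlog + cv$sdlog * zj)
        } else {
          cv$mean + cv$sd * zj
        },
        binary = as.integer(zj > qnorm(1 - cv$prob)),
        categorical = {
          breaks <- c(0, cumsum(cv$probs) / sum(cv$probs))
          cut(pnorm(zj),
            breaks = breaks, labels = cv$levels,
            include.lowest = TRUE
          )
        },
        abort(sprintf("Unknown covariate kind '%s'.", cv$kind))
      )
    }
    out$response_quartile <- if (spec$response_log_sd == 0) {
      suppressWarnings(assign_quartiles(response))
    } else {
      assign_quartiles(response)
    }
    attr(out, "response_name") <- spec$response_name
    class(out) <- c("cohort_table", class(out))
    out
  })
}

#' Specify a synthetic omics block
#'
#' @param name Block label (also seeds the block's RNG sub-stream).
#' @param kind `"counts"` (Dirichlet-multinomial compositional counts) or
#'   `"intensity"` (log-normal intensities).
#' @param n_features Number of features.
#' @param baseline_log_abundance Either a numeric vector of length
#'   `n_features`, or a list `list(mean =, sd =)` from which baselines are
#'   drawn.
#' @param dispersion For counts: the Dirichlet-multinomial concentration
#'   (smaller = more overdispersed; default 50). For intensities: the
#'   log-scale residual sd (default 0.6).
#' @param depth For counts: list `list(meanlog =, sdlog =)` of the
#'   log-normal sequencing-depth distribution (rounded, floored at 100).
#' @param planted_effects Data frame with columns `feature` (index in
#'   `1..n_features`) and `beta`: the per-unit shift of the feature's
#'   log-abundance per standard deviation of log response.
#' @param cross_block_links Data frame with columns `feature`,
#'   `other_block`, `other_feature`, `loading`: both linked features load on
#'   a shared standard-normal latent factor with the given loading.
#' @param count_model `"dirichlet_multinomial"` (default) or
#'   `"logistic_normal"` (log-normal-softmax alternative).
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(name, kind = c("counts", "intensity"), n_features,
                       baseline_log_abundance = NULL,
                       dispersion = NULL,
                       depth = list(meanlog = log(2e4), sdlog = 0.25),
                       planted_effects = NULL,
                       cross_block_links = NULL,
                       count_model = c("dirichlet_multinomial", "logistic_normal")) {
  kind <- match.arg(kind)
  count_model <- match.arg(count_model)
  if (n_features < 1) abort("`n_features` must be positive.")
  if (is.null(dispersion)) dispersion <- if (kind == "counts") 50 else 0.6
  if (dispersion <= 0) abort("`dispersion` must be positive.")
  if (is.null(baseline_log_abundance)) {
    baseline_log_abundance <- if (kind == "counts") {
      list(mean = 0, sd = 1.5)
    } else {
      list(mean = 5, sd = 1)
    }
  }
  if (is.numeric(baseline_log_abundance) &&
      length(baseline_log_abundance) != n_features) {
    abort("`baseline_log_abundance` vector must have length `n_features`.")
  }
  if (!is.null(planted_effects)) {
    planted_effects <- as_tibble(planted_effects)
    stopifnot(all(c("feature", "beta") %in% names(planted_effects)))
    if (anyDuplicated(planted_effects$feature)) {
      abort("Planted feature indices must be unique.")
    }
    if (any(planted_effects$feature < 1 | planted_effects$feature > n_features)) {
      abort("Planted feature index out of range.")
    }
  }
  if (!is.null(cross_block_links)) {
    cross_block_links <- as_tibble(cross_block_links)
    stopifnot(all(c("feature", "other_block", "other_feature", "loading") %in%
      names(cross_block_links)))
    if (any(cross_block_links$feature < 1 |
            cross_block_links$feature > n_features)) {
      abort("Linked feature index out of range.")
    }
  }
  structure(
    list(
      name = name, kind = kind, n_features = as.integer(n_features),
      baseline_log_abundance = baseline_log_abundance,
      dispersion = dispersion, depth = depth,
      planted_effects = planted_effects,
      cross_block_links = cross_block_links,
      count_model = count_model
    ),
    class = "block_spec"
  )
}

resolve_baseline <- function(spec) {
  if (is.numeric(spec$baseline_log_abundance)) {
    spec$baseline_log_abundance
  } else {
    rnorm(
      spec$n_features,
      mean = spec$baseline_log_abundance$mean,
      sd = spec$baseline_log_abundance$sd
    )
  }
}

#' Generate one omics block for a cohort
#'
#' The per-sample, per-feature log-abundance is
#' `baseline_j + beta_j * z_s + sum(loading * h_s)` where `z_s` is the
#' standardized log response and `h_s` are shared latent link factors. For
#' counts the log-abundances are soft-maxed into a composition and drawn
#' Dirichlet-multinomial at the sample's sequencing depth; for intensities
#' they receive log-normal noise and are exponentiated.
#'
#' @param cohort A cohort table from [generate_cohort()].
#' @param spec A [block_spec()].
#' @param seed Integer master seed; the block draws from a sub-stream
#'   derived from `seed` and the block name.
#' @param latent Optional named list of per-sample latent factor vectors for
#'   cross-block links (supplied by [simulate_dataset()]).
#' @return An [omics_block()].
#' @export
generate_block <- function(cohort, spec, seed = 1, latent = NULL) {
  if (!inherits(spec, "block_spec")) abort("`spec` must be a block_spec.")
  if (!nrow(cohort)) abort("`cohort` must be nonempty.")
  response_name <- attr(cohort, "response_name") %||% "ferritin"
  y <- cohort[[response_name]]
  n <- length(y)
  ly <- log(y)
  z <- if (sd(ly) == 0) rep(0, n) else (ly - mean(ly)) / sd(ly)

  with_seed(derive_seed(seed, paste0("block:", spec$name)), {
    baseline <- resolve_baseline(spec)
    eta <- matrix(baseline, nrow = n, ncol = spec$n_features, byrow = TRUE)
    if (!is.null(spec$planted_effects)) {
      for (i in seq_len(nrow(spec$planted_effects))) {
        j <- spec$planted_effects$feature[i]
        eta[, j] <- eta[, j] + spec$planted_effects$beta[i] * z
      }
    }
    if (!is.null(spec$cross_block_links) && !is.null(latent)) {
      for (i in seq_len(nrow(spec$cross_block_links))) {
        key <- link_key(
          spec$name, spec$cross_block_links$feature[i],
          spec$cross_block_links$other_block[i],
          spec$cross_block_links$other_feature[i]
        )
        h <- latent[[key]]
        if (is.null(h)) abort(sprintf("No latent factor supplied for link %s.", key))
        j <- spec$cross_block_links$feature[i]
        eta[, j] <- eta[, j] + spec$cross_block_links$loading[i] * h
      }
    }
    values <- if (spec$kind == "counts") {
      depth <- pmax(100, round(rlnorm(n, spec$depth$meanlog, spec$depth$sdlog)))
      counts <- matrix(0L, n, spec$n_features)
      for (s in seq_len(n)) {
        pr <- exp(eta[s, ] - max(eta[s, ]))
        pr <- pr / sum(pr)
        pi_s <- if (spec$count_model == "dirichlet_multinomial") {
          g <- rgamma(spec$n_features, shape = spec$dispersion * pr, rate = 1)
          if (sum(g) == 0) pr else g / sum(g)
        } else {
          e <- exp(eta[s, ] + rnorm(spec$n_features, 0, spec$dispersion) -
            max(eta[s, ]))
          e / sum(e)
        }
        counts[s, ] <- rmultinom(1, depth[s], pi_s)[, 1]
      }
      counts
    } else {
      exp(eta + matrix(rnorm(n * spec$n_features, 0, spec$dispersion),
        n, spec$n_features
      ))
    }
    rownames(values) <- cohort$sample_id
    colnames(values) <- sprintf("%s_f%04d", spec$name, seq_len(spec$n_features))
    omics_block(values, kind = spec$kind, name = spec$name)
  })
}

link_key <- function(block_a, feature_a, block_b, feature_b) {
  a <- sprintf("%s:%d", block_a, feature_a)
  b <- sprintf("%s:%d", block_b, feature_b)
  paste(sort(c(a, b)), collapse = "~")
}

#' Simulate a full multi-omics dataset
#'
#' Generates the cohort, draws one shared latent factor per distinct
#' cross-block link, generates every block from its own seed sub-stream
#' (derived from the master seed and block name, so adding a block never
#' perturbs earlier blocks), and records the ground truth of all planted
#' effects and links.
#'
#' @param cohort_spec A [cohort_spec()].
#' @param block_specs List of [block_spec()]s.
#' @param seed Master seed (defaults to the cohort spec's seed).
#' @return An object of class `synthetic_dataset`: `cohort`, named list
#'   `blocks`, `truth` tibble and `seed`.
#' @export
simulate_dataset <- function(cohort_spec, block_specs = list(), seed = cohort_spec$seed) {
  cohort <- generate_cohort(cohort_spec, seed = seed)
  link_keys <- character(0)
  for (bs in block_specs) {
    if (!is.null(bs$cross_block_links)) {
      for (i in seq_len(nrow(bs$cross_block_links))) {
        link_keys <- union(link_keys, link_key(
          bs$name, bs$cross_block_links$feature[i],
          bs$cross_block_links$other_block[i],
          bs$cross_block_links$other_feature[i]
        ))
      }
    }
  }
  latent <- lapply(setNames(link_keys, link_keys), function(k) {
    with_seed(derive_seed(seed, paste0("link:", k)), rnorm(nrow(cohort)))
  })
  blocks <- list()
  truth <- list()
  for (bs in block_specs) {
    blocks[[bs$name]] <- generate_block(cohort, bs, seed = seed, latent = latent)
    if (!is.null(bs$planted_effects) && nrow(bs$planted_effects)) {
      truth[[length(truth) + 1]] <- tibble(
        type = "response_effect", block = bs$name,
        feature_id = sprintf("%s_f%04d", bs$name, bs$planted_effects$feature),
        feature = bs$planted_effects$feature,
        beta = bs$planted_effects$beta,
        partner_block = NA_character_, partner_feature = NA_integer_,
        loading = NA_real_
      )
    }
    if (!is.null(bs$cross_block_links) && nrow(bs$cross_block_links)) {
      truth[[length(truth) + 1]] <- tibble(
        type = "cross_block_link", block = bs$name,
        feature_id = sprintf("%s_f%04d", bs$name, bs$cross_block_links$feature),
        feature = bs$cross_block_links$feature,
        beta = NA_real_,
        partner_block = bs$cross_block_links$other_block,
        partner_feature = as.integer(bs$cross_block_links$other_feature),
        loading = bs$cross_block_links$loading
      )
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else tibble(
    type = character(), block = character(), feature_id = character(),
    feature = integer(), beta = numeric(), partner_block = character(),
    partner_feature = integer(), loading = numeric()
  )
  structure(
    list(cohort = cohort, blocks = blocks, truth = truth, seed = seed),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d samples, %d block(s), %d planted effect(s)/link(s)\n",
    nrow(x$cohort), length(x$blocks), nrow(x$truth)
  ))
  for (b in x$blocks) print(b)
  invisible(x)
}
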