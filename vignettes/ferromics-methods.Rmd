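---
title: "Multi-omics association discovery with ferromics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics association discovery with ferromics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferromics)
```

## The scientific problem

Cohort studies that relate a continuous phenotype — serum ferritin, the
iron-storage proxy, in the motivating setting — to high-dimensional omics
blocks (gut microbial taxa, circulating metabolites, tissue transcripts)
face three linked statistical problems: far more features than samples,
strong collinearity within each block, and confounding by host covariates
such as age, BMI, sex, country and inflammation (hs-CRP). ferromics
implements a discovery → validation → confirmation workflow for exactly
this setting, plus the two-block integration and ecology summaries that
usually accompany it, and a synthetic-cohort generator that makes every
stage testable without access to any cohort data.

## The discovery engine: single-response O-PLS

The core model is orthogonal projections to latent structures (O-PLS) with
one predictive component. After centering and unit-variance scaling of the
feature matrix $X$ (the response $y$ is centered only), each orthogonal
component is extracted as

$$w \propto X^\top y,\quad t = Xw,\quad p = X^\top t / t^\top t,\quad
  w_o \propto p - (w^\top p)\,w,$$

followed by deflation of $X$ with the orthogonal score/loading pair; the
predictive component is then fitted on the deflated matrix and the
regression scalar $b = t^\top y / t^\top t$ closes the model. With zero
orthogonal components the model coincides with 1-component PLS1 (NIPALS),
an identity the test suite checks against an independent implementation at
`1e-10`.

**Model quality.** $R^2Y$ is the training variance explained; $Q^2Y$ is
the cross-validated analogue, $1 - \mathrm{PRESS}/SS_{tot}$, computed
leave-one-out with centering and scaling re-estimated inside every fold.
**Validity** is established by permutation: the response is shuffled, the
model and its $Q^2Y$ recomputed, and the p-value uses the +1-smoothed
estimator $(1 + \#\{\text{null} \ge \text{observed}\})/(1 + B)$, which can
never return 0. Downstream feature selection runs only when the
permutation p-value for $Q^2Y$ passes a gate (default 0.05, configurable).

**Feature selection** combines two signals. Each feature's loading is
rescaled as its Pearson correlation with the predictive score (the SUS-plot
convention) and tested two-sided on $n-2$ degrees of freedom, then
BH-adjusted across features. Variable importance in projection (VIP) is
the predictive-component variant, $\sqrt{p}\,|w_j|$, whose squares average
exactly 1; a total variant that folds in the orthogonal components
(weighted by explained X-variance) is available behind a flag. A feature
is selected when $p_{FDR} < 0.05$, or when $p_{FDR} < 0.10$ and VIP $> 1$.
Every selected feature is finally **confirmed** by covariate-adjusted
partial Spearman correlation against the response (raw $p < 0.05$).

### Known property: circular loading tests

Testing features against a score assembled from those same features is
circular: on pure-noise data the loading-correlation test over-fires
relative to its nominal FDR, for any number of features, because the score
chases in-sample noise correlations. The workflow's protection is layered:
the permutation gate rejects the model itself on null data (the end-to-end
suite measures a gate-failure rate above 90%), and pSC confirmation prunes
the selections that survive. Users should treat the selection table of a
*gated-out* model as meaningless, which is why the pipeline refuses to
produce one.

## Two-block integration: O2-PLS

For a pair of blocks (for example response-associated transcripts against
response-associated taxa), O2-PLS decomposes each block into joint,
block-specific (orthogonal) and residual parts. Joint weights are the
leading singular vectors of $X^\top Y$; per-block orthogonal components
are estimated from the residual of the joint reconstruction and removed;
the inner relation $U = TB$ is a least-squares fit between the joint score
matrices. Component counts are chosen by k-fold cross-validation (default
7 folds) of the *symmetric* prediction error — held-out $Y$ from $X$ plus
held-out $X$ from $Y$, each normalized by the held-out block's total sum
of squares — because the model describes joint variation, not a directed
regression. Ties break toward the smallest total component count. Joint
loadings are reported correlation-scaled (`pcorr`/`qcorr`): the Pearson
correlation of each variable with its block's joint score, which places
variables on a correlation circle where ~0° separation means positive
association, ~180° negative, ~90° none.

## Covariate-adjusted sparse selection: Mnet

The penalized alternative for count tables is Mnet: minimax concave
penalty (MCP) plus ridge, which performs sparse selection while tolerating
the strong collinearity of taxa tables. On standardized features the
univariate subproblem has the closed-form solution

$$\hat\beta = \begin{cases}
  S(z, \lambda_1) / (1 + \lambda_2 - 1/\gamma) & |z| \le \gamma\lambda_1(1+\lambda_2)\\
  z / (1 + \lambda_2) & \text{otherwise,}
\end{cases}$$

with $\lambda_1 = \alpha\lambda$, $\lambda_2 = (1-\alpha)\lambda$ and the
convexity condition $\gamma(1+\lambda_2) > 1$ enforced. Fitting is cyclic
coordinate descent with a $1/(2n)$ loss, covariates (age, BMI, country,
hs-CRP — dummy-encoded, never standardized away from interpretability)
updated by unpenalized least-squares steps, and convergence declared when
the largest standardized-coefficient change falls below `1e-7`. In debug
mode every sweep asserts that the penalized objective did not increase.
Limits anchor the implementation: $\lambda = 0$ reproduces OLS,
$\gamma \to \infty$ with $\alpha = 1$ reproduces the LASSO (checked
against glmnet), and on small instances the solution matches a
derivative-free global minimizer of the objective. Tuning is k-fold
cross-validation (default 10 folds) over $(\lambda, \alpha, \gamma)$ with
warm starts along each descending $\lambda$ path and ties broken toward
the sparser model; default grids are a 100-point log-spaced $\lambda$ path
from $\lambda_{max}$ down to $0.001\lambda_{max}$, $\alpha \in
\{0.1,\dots,0.9\}$ and $\gamma \in \{2.5, 3, 8\}$.

## Univariate statistics

* **Partial Spearman (pSC):** rank $x$ and $y$ (average ranks), rank
  continuous covariates, dummy-encode categorical ones, residualize both
  ranked variables on the covariate design, and correlate the residuals.
  The p-value uses $t = \rho\sqrt{(n-2-k)/(1-\rho^2)}$ on $n-2-k$ degrees
  of freedom — the t-approximation, chosen because it is the standard
  finite-sample reference for partial rank correlations.
* **Mann-Kendall trend across quartiles:** implemented as Kendall's
  tau-b between the ordered group index and the value, i.e.
  $S = \sum_{i<j} \mathrm{sign}(g_j - g_i)\,\mathrm{sign}(v_j - v_i)$ with
  the full tie-corrected variance and a ±1 continuity-corrected normal
  statistic — the natural reading of a trend test applied to grouped
  cross-sectional data.
* **Wilcoxon-Mann-Whitney:** exact enumeration when the combined sample
  size is at most 20 and there are no ties, otherwise the tie-corrected,
  continuity-corrected normal approximation.
* **Quartiles:** type-7 (linear interpolation) percentile cuts at
  25/50/75%, with boundary values assigned to the lower quartile.
* **Over-representation:** upper-tail hypergeometric $P(X \ge k)$ per gene
  set (GMT input), Bonferroni-corrected by default, BH optionally.

## Ecology summaries

Shannon entropy is computed in nats via vegan; observed species is the
positive-count tally; Chao1 defaults to the bias-corrected form
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (defined even with no doubletons), with
the classic $S_{obs} + F_1^2/(2F_2)$ behind a flag. Canberra distance uses
the unscaled sum $\sum |x_i-y_i|/(x_i+y_i)$ over coordinates where the
pair is not both zero (so Canberra([1,0],[0,1]) = 2); note vegan's
`vegdist` divides by the number of contributing coordinates and would give
1 — the unscaled convention is deliberate. Bray-Curtis pairs involving an
all-zero sample are set to distance 1 with a warning. PCoA is classical
scaling: negative eigenvalues are reported but excluded from the
proportion-explained denominator, and no Lingoes/Cailliez correction is
applied. PERMANOVA is the one-way Anderson partitioning of squared
distances with seeded label permutations and the +1-smoothed p; an exact
mode enumerates all distinct relabelings on small inputs. Hierarchical
clustering is Ward.D2 on Euclidean distances of z-scored data, for both
samples and features.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; it emulates the post-processing feature tables of a
ferritin-style cohort, not raw sequencing.

* **Response:** log-normal. The defaults (`meanlog = log(80)`,
  `sdlog = 0.8`) produce the right-skewed, strictly positive distribution
  typical of serum ferritin in mixed cohorts; they are free parameters of
  the generator, not estimates of any published cohort, which does not
  report its distribution parameters.
* **Covariates:** age and BMI as continuous normals (43 ± 9 years,
  30 ± 5 kg/m²), sex balanced binary, country two-level, hs-CRP
  log-normal. Confounding is induced by a Gaussian copula — each
  covariate's latent normal is mixed with the response's latent normal at
  a requested correlation — so arbitrary marginals carry a controlled
  rank correlation. Continuous normal covariates reproduce the requested
  Pearson correlation with the log response exactly (up to Monte-Carlo
  error); discretized covariates realize an attenuated version, as
  discretization always does. Defaults: age 0.2, BMI 0.15, hs-CRP 0.3.
* **Counts blocks:** per-sample log-composition = baseline + planted
  shifts, soft-maxed and drawn Dirichlet-multinomial at a log-normal
  sequencing depth (default concentration 50, depth `meanlog = log(2e4)`,
  `sdlog = 0.25`, floored at 100 reads). The Dirichlet-multinomial
  captures the overdispersion and compositionality of shotgun-derived
  taxa tables; a logistic-normal-softmax alternative sits behind a flag.
* **Intensity blocks:** log-normal around per-feature baselines (default
  residual sd 0.6 on the log scale).
* **Planted effects:** $\beta$ shifts a feature's log-abundance per
  standard deviation of log response, making $\beta$ unit-free.
  **Cross-block links** are realized through shared standard-normal latent
  factors that both linked features load on.
* **Seeding:** one master seed; every component (cohort, each block, each
  link factor) draws from a sub-stream derived from the master seed and
  the component's label, so adding a block never perturbs earlier blocks.

**What the generator does not emulate:** taxonomic correlation structure
(phylogenetic relatedness), zero-inflation beyond what the
Dirichlet-multinomial produces, batch effects, measurement drift, or
nonlinear response-feature relationships. Passing the recovery tests
therefore demonstrates that the pipeline machinery is correct and
calibrated under its own assumptions — not that it would achieve the same
sensitivity on real cohort data.

### Planting effects in compositional data

A recovery benchmark on compositional counts must keep the planted mass
share modest. If a planted taxon draws a dominant baseline (a few percent
of total reads), closure transfers its response-driven swings to every
other taxon: null taxa then *genuinely* anti-correlate with the response,
and "false discovery versus planted truth" stops being well-defined. The
end-to-end validation therefore plants balanced signs (five taxa at
$\beta=+2$, five at $\beta=-2$, mirroring the mix of enriched and depleted
taxa reported in ferritin cohorts) on taxa pinned to the baseline
distribution's center. Under those conditions the null taxa's correlation
distribution is indistinguishable from a no-effect dataset.

## Pipeline defaults and why

| parameter | default | rationale |
|---|---|---|
| filter (counts blocks) | rel. abundance > 0.001 in ≥ 20% of samples | detection-level prevalence rule; the published "> 20% abundance in ≥ 20% of samples" is available verbatim via `filter_features()` or the config, but taken literally it removes nearly every taxon from a realistic table, so it is not a usable pipeline default |
| pseudocount | half the smallest nonzero value per block | data-derived, deterministic, keeps log10 defined |
| `n_orth` | 1 (or `"auto"`) | the source models never report their orthogonal-component counts; one component is the common chemometrics default, and auto mode adds components while LOO $Q^2Y$ improves by > 0.01 |
| permutations | 1000 | the validation convention of the motivating study |
| gate | permutation $p(Q^2Y) < 0.05$ | a model must predict better than chance before its loadings are interpreted |
| selection | $p_{FDR}<0.05$, or $p_{FDR}<0.10$ with VIP > 1 | the published rule, verbatim |
| confirmation | pSC raw $p < 0.05$, covariates age/BMI/sex/country | the published heatmap convention; the FDR-highlighted subset is also reported |
| O2-PLS CV | 7 folds, orthogonal grids 0–2 | folds as published; the orthogonal grid is unreported, so a small default |
| Mnet CV | 10 folds | as published |

The test suite and the acceptance script run the permutation stages with
199 or fewer permutations and 7- or 10-fold Q2 inside the permutation
loop, at cohort sizes of 100–200 samples and 100–200 features. These are
the package's validation problem sizes: large enough that calibration and
recovery rates are measured meaningfully, small enough that the whole
suite re-runs in minutes. Permutation-test calibration is invariant to
the choice of CV scheme inside the loop, which the calibration suite
verifies empirically.

## Numerical choices and degenerate inputs

* Zero-variance features are dropped with a warning before latent-variable
  fits; constant responses are an error.
* The O-PLS orthogonal extraction stops early (keeping a zero component)
  when no orthogonal variation remains, e.g. for a univariate predictor.
* Permutation and PERMANOVA p-values use the +1-smoothed estimator and
  never return 0; exceedance comparisons use a `1e-12` slack so exact ties
  (identity relabelings) count as exceedances.
* Quartile ties go to the lower quartile; an all-constant vector is all-Q1
  with a warning.
* Wilcoxon on two identical tied samples would give a 0/0 normal
  statistic; the p-value is defined as 1 (no evidence).
* CV fold assignment is a seeded shuffle of the cyclic pattern
  `1, 2, ..., k, 1, 2, ...`; all seeds derive from the master seed plus a
  component label, so results are bit-reproducible and stage outputs are
  pure functions of (inputs, config, seed).
* TSV serialization writes doubles at 17 significant digits (`%.17g`) and
  reads them with the correctly-rounded base-R parser, so write → read
  round-trips are exact; report tables are written at 12 significant
  digits.

## Limitations

* The loading-significance test inherits the circularity of the published
  procedure (see above); interpret selection tables only for
  permutation-validated models, and prefer the confirmed (pSC) set.
* PERMANOVA is one-way only; no strata, no covariates, no multi-factor
  designs (vegan's `adonis2` covers those needs).
* O2-PLS is two-block; multi-block extensions are out of scope.
* UniFrac and any phylogeny-aware diversity are out of scope (no tree).
* The Mnet implementation is Gaussian-response only — no GLM variants,
  group penalties or SCAD.
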