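# Univariate confirmation statistics: partial Spearman, BH, Mann-Kendall,
# Wilcoxon and over-representation.

test_that("partial Spearman reduces to ordinary Spearman without covariates", {
  res <- partial_spearman(c(1, 2, 3), c(3, 1, 2))
  expect_equal(res$estimate, -0.5)

  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(25)
    y <- rnorm(25)
    expect_equal(
      partial_spearman(x, y)$estimate,
      cor(x, y, method = "spearman"),
      tolerance = 1e-12
    )
  }
})

test_that("partial Spearman matches the rank-residualization oracle", {
  set.seed(2)
  for (i in 1:10) {
    n <- 40
    z <- cbind(age = rnorm(n), bmi = rnorm(n))
    x <- rnorm(n) + z[, 1]
    y <- rnorm(n) + z[, 1]
    ours <- partial_spearman(x, y, as.data.frame(z))$estimate
    ref <- oracle_partial_spearman(x, y, cbind(rank(z[, 1]), rank(z[, 2])))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("partial Spearman is symmetric and monotone-invariant", {
  set.seed(3)
  n <- 30
  z <- data.frame(age = rnorm(n))
  x <- rexp(n)
  y <- rnorm(n)
  expect_equal(
    partial_spearman(x, y, z)$estimate,
    partial_spearman(y, x, z)$estimate,
    tolerance = 1e-12
  )
  expect_equal(
    partial_spearman(x, y, z)$estimate,
    partial_spearman(log(x), exp(y / 3), z)$estimate,
    tolerance = 1e-12
  )
})

test_that("adjusting for a shared confounder shrinks the correlation", {
  set.seed(4)
  n <- 200
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)
  plain <- abs(partial_spearman(x, y)$estimate)
  partial <- abs(partial_spearman(x, y, data.frame(z = z))$estimate)
  expect_lt(partial, plain)
})

test_that("categorical covariates are dummy-encoded, not ranked", {
  set.seed(5)
  n <- 60
  country <- factor(sample(c("IT", "ES", "FR"), n, replace = TRUE))
  shift <- c(IT = 0, ES = 2, FR = -1)[as.character(country)]
  x <- rnorm(n) + shift
  y <- rnorm(n) + shift
  res <- partial_spearman(x, y, data.frame(country = country))
  expect_equal(res$df, n - 2 - 2) # two dummy columns
  expect_lt(abs(res$estimate), abs(partial_spearman(x, y)$estimate))
})

test_that("constant inputs are refused", {
  expect_error(partial_spearman(rep(1, 10), rnorm(10)), "constant")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)), c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # order preservation
  p <- runif(30)
  expect_identical(order(bh_adjust(p)[order(p)]), seq_len(30))
})

test_that("Mann-Kendall detects perfect monotone trends exactly", {
  up <- mann_kendall_trend(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_identical(up$S, 6L)
  expect_equal(up$tau, 1)
  down <- mann_kendall_trend(c(4, 3, 2, 1), c(1, 2, 3, 4))
  expect_identical(down$S, -6L)
  expect_equal(down$tau, -1)
  expect_equal(up$p.value, down$p.value, tolerance = 1e-12)
  expect_error(mann_kendall_trend(1:4, rep(1, 4)), "distinct groups")
})

test_that("grouped tau-b matches cor.test under ties", {
  set.seed(7)
  for (i in 1:5) {
    g <- sample(1:4, 40, replace = TRUE)
    v <- rnorm(40) + 0.3 * g
    ours <- mann_kendall_trend(v, g)
    ref <- suppressWarnings(cor.test(g, v, method = "kendall"))
    expect_equal(ours$tau, unname(ref$estimate), tolerance = 1e-10)
  }
})

test_that("Mann-Kendall p-values are calibrated under the null", {
  set.seed(8)
  g <- rep(1:4, each = 10)
  pvals <- replicate(300, mann_kendall_trend(rnorm(40), g)$p.value)
  # S is integer-valued, so p-values are mildly discrete; the KS check is
  # conservative under discreteness
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("Wilcoxon exact mode matches full enumeration", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p.value, 1 / 3, tolerance = 1e-12)
  expect_identical(res$method, "exact")

  a <- c(5, 5, 5)
  expect_equal(wilcoxon_rank_sum(a, a)$p.value, 1)

  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(6)
    b <- rnorm(5) + 0.5
    expect_equal(
      wilcoxon_rank_sum(a, b, mode = "exact")$p.value,
      oracle_wilcoxon_exact(a, b),
      tolerance = 1e-12
    )
  }
})

test_that("normal approximation tracks the exact p for moderate n", {
  set.seed(10)
  for (i in 1:10) {
    a <- rnorm(10)
    b <- rnorm(10)
    p_exact <- wilcoxon_rank_sum(a, b, mode = "exact")$p.value
    p_norm <- wilcoxon_rank_sum(a, b, mode = "normal")$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("hypergeometric ORA matches enumeration and handles edge cases", {
  universe <- paste0("g", 1:20)
  sets <- list(setA = paste0("g", 1:5))
  selected <- c("g1", "g2", "g3", "g10", "g11")
  res <- hypergeom_ora(selected, sets, universe)
  expect_equal(res$p.value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$p.value, oracle_hypergeom_tail(3, 5, 5, 20), tolerance = 1e-12)
  expect_identical(res$overlap, 3L)

  # zero overlap -> p = P(X >= 0) = 1
  res0 <- hypergeom_ora(paste0("g", 10:14), sets["setA"], universe)
  expect_equal(res0$p.value, oracle_hypergeom_tail(0, 5, 5, 20))
  expect_equal(hypergeom_ora(paste0("g", 6:10), list(s = paste0("g", 1:5)),
    universe
  )$p.value, 1)

  # selected = universe forces k = K and p = 1 for every set
  resall <- hypergeom_ora(universe, list(a = paste0("g", 1:5), b = paste0("g", 3:9)), universe)
  expect_true(all(resall$overlap == resall$set_size))
  expect_true(all(resall$p.value == 1))

  # corrections
  many <- list(a = paste0("g", 1:5), b = paste0("g", 6:10), c = paste0("g", 11:15))
  bonf <- hypergeom_ora(selected, many, universe, correction = "bonferroni")
  expect_equal(bonf$p_adjusted, pmin(1, bonf$p.value * 3))

  expect_error(hypergeom_ora(c("g1", "zz"), sets, universe), "subset")
  expect_error(hypergeom_ora("g1", sets, character(0)), "nonempty")
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "pathA\tdesc\tg1\tg2\tg3",
    "pathB\tother\tg4\tg5"
  ), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("pathA", "pathB"))
  expect_identical(sets$pathA, c("g1", "g2", "g3"))
})
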