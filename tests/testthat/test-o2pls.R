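# O2-PLS: block decomposition identities, planted-factor recovery,
# cross-validated component selection and correlation-scaled loadings.

test_that("identical blocks are explained by their joint components", {
  set.seed(1)
  x <- matrix(rnorm(40 * 6), 40, 6)
  fit <- fit_o2pls(x, x, n_joint = 2, scaling = "none")
  v <- fit$variance

  # rank-2 truncation share of the centered matrix
  xc <- scale(x, scale = FALSE)
  ev <- svd(xc)$d^2
  rank2_share <- sum(ev[1:2]) / sum(ev)
  expect_gte(v$joint[1], 0.999 * rank2_share)
  expect_gte(v$joint[2], 0.999 * rank2_share)

  # inner relation is the identity: U = T exactly
  expect_lt(max(abs(fit$u - fit$t %*% fit$b_t)), 1e-8)
})

test_that("joint loadings are orthonormal and variance parts are coherent", {
  set.seed(2)
  x <- matrix(rnorm(30 * 8), 30, 8)
  y <- matrix(rnorm(30 * 5), 30, 5)
  fit <- fit_o2pls(x, y, n_joint = 2, n_xorth = 1, n_yorth = 1)
  expect_equal(crossprod(fit$w), diag(2), tolerance = 1e-10)
  expect_equal(crossprod(fit$c), diag(2), tolerance = 1e-10)
  v <- fit$variance
  expect_true(all(v$joint >= 0 & v$orthogonal >= 0))
  expect_true(all(v$joint + v$orthogonal <= 1 + 1e-8))
})

test_that("a planted shared factor is recovered in the first joint score", {
  set.seed(3)
  n <- 60
  h <- rnorm(n)
  x <- outer(h, runif(10, 0.5, 1)) + matrix(rnorm(n * 10, sd = 0.3), n)
  y <- outer(h, runif(7, 0.5, 1)) + matrix(rnorm(n * 7, sd = 0.3), n)
  fit <- fit_o2pls(x, y, n_joint = 1)
  expect_gt(abs(cor(fit$t[, 1], h)), 0.9)
  expect_gt(abs(cor(fit$u[, 1], h)), 0.9)
})

test_that("independent blocks yield no out-of-sample joint prediction", {
  set.seed(4)
  r2s <- replicate(5, {
    x <- matrix(rnorm(50 * 8), 50, 8)
    y <- matrix(rnorm(50 * 8), 50, 8)
    train <- 1:40
    fit <- fit_o2pls(x[train, ], y[train, ], n_joint = 1)
    yhat <- predict(fit, x[-train, ], direction = "y_from_x")
    resid <- y[-train, ] - yhat
    1 - sum(resid^2) / sum(scale(y[-train, ], scale = FALSE)^2)
  })
  expect_lte(median(r2s), 0.05)
})

test_that("with one joint and no orthogonal components X-scores match PLS", {
  set.seed(5)
  x <- matrix(rnorm(25 * 6), 25, 6)
  y <- matrix(rnorm(25 * 4), 25, 4)
  y[, 1] <- y[, 1] + x[, 1]
  fit <- fit_o2pls(x, y, n_joint = 1, scaling = "uv")
  ref <- oracle_pls2_xscore(x, y)
  # sign-indeterminate: align before comparing
  s <- sign(sum(fit$t[, 1] * ref))
  expect_equal(as.numeric(fit$t[, 1]) * s, ref, tolerance = 1e-8)
})

test_that("the fit is invariant to within-block feature permutation", {
  set.seed(6)
  x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("a", 1:5)))
  y <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("b", 1:4)))
  f1 <- fit_o2pls(x, y, n_joint = 1)
  f2 <- fit_o2pls(x[, c(4, 2, 5, 1, 3)], y, n_joint = 1)
  s <- sign(sum(f1$t[, 1] * f2$t[, 1]))
  expect_equal(f1$t[, 1] * s, f2$t[, 1], tolerance = 1e-8)
  expect_equal(f1$variance$joint, f2$variance$joint, tolerance = 1e-10)
})

test_that("cross-validation picks the planted number of joint components", {
  set.seed(7)
  picks <- replicate(10, {
    n <- 50
    h <- matrix(rnorm(n * 2), n, 2)
    lx <- matrix(runif(2 * 8, 0.6, 1.2), 2, 8)
    ly <- matrix(runif(2 * 6, 0.6, 1.2), 2, 6)
    x <- h %*% lx + matrix(rnorm(n * 8, sd = 0.25), n)
    y <- h %*% ly + matrix(rnorm(n * 6, sd = 0.25), n)
    cv <- crossval_o2pls(x, y, n_joint = 1:3, n_xorth = 0, n_yorth = 0,
                         folds = 5, seed = sample.int(1e6, 1))
    cv$best$n_joint
  })
  expect_gte(mean(picks == 2), 0.8)
})

test_that("pure noise selects the least complex grid point", {
  set.seed(8)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- matrix(rnorm(40 * 6), 40, 6)
  cv <- crossval_o2pls(x, y, n_joint = 1:2, n_xorth = 0:1, n_yorth = 0:1,
                       folds = 5, seed = 1)
  expect_identical(
    nrow(cv$surface),
    8L
  )
  expect_lte(cv$best$n_joint + cv$best$n_xorth + cv$best$n_yorth, 2)
})

test_that("correlation loadings are correlations with the joint scores", {
  set.seed(9)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- matrix(rnorm(40 * 4), 40, 4)
  y[, 2] <- x[, 1] + rnorm(40, sd = 0.2)
  fit <- fit_o2pls(x, y, n_joint = 1)
  cl <- correlation_loadings(fit, x, y)

  # definition check and range
  expect_equal(cl$pcorr$comp1, as.numeric(cor(x, fit$t[, 1])), tolerance = 1e-12)
  expect_true(all(abs(cl$pcorr$comp1) <= 1, abs(cl$qcorr$comp1) <= 1))

  # a feature equal to its own score has correlation loading 1
  x2 <- cbind(x, fit$t[, 1])
  fit2 <- fit_o2pls(x2, y, n_joint = 1)
  cl2 <- correlation_loadings(fit2, x2, y)
  expect_gt(abs(cl2$pcorr$comp1[6]), 0.999)

  # for UV-scaled data the sign of pcorr matches the sign of the projection
  # loading X't (same numerator, positive denominators)
  proj_loading <- as.numeric(crossprod(scale(x), fit$t[, 1]))
  expect_equal(sign(cl$pcorr$comp1), sign(proj_loading))
})

test_that("zero-variance features get zeroed loadings with a warning", {
  set.seed(10)
  x <- cbind(matrix(rnorm(60), 20, 3), 5)
  y <- matrix(rnorm(40), 20, 2)
  fit <- fit_o2pls(x[, 1:3], y, n_joint = 1)
  expect_warning(cl <- correlation_loadings(fit, x[, c(1, 2, 4)], y), "Zero-variance")
  expect_equal(cl$pcorr$comp1[3], 0)
})

test_that("mismatched samples are rejected", {
  x <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  y <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("t", 1:10), NULL))
  expect_error(fit_o2pls(x, y, n_joint = 1), "identifiers")
  expect_error(fit_o2pls(x[1:8, ], matrix(rnorm(30), 10, 3), n_joint = 1), "same samples")
})
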