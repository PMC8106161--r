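# Mnet (MCP + ridge) regression: the thresholding operator, coordinate
# descent limits, objective monotonicity and cross-validated tuning.

test_that("the thresholding operator matches the closed form and a grid oracle", {
  expect_equal(mnet_threshold(1.5, 1, 0, 3), 0.75)
  expect_equal(mnet_threshold(3, 1, 0, 3), 3)
  expect_equal(mnet_threshold(-1.5, 1, 0, 3), -0.75)
  # pure ridge limit
  expect_equal(mnet_threshold(2, 0, 0.5, 3), 2 / 1.5)

  set.seed(1)
  for (i in 1:25) {
    z <- runif(1, -4, 4)
    l1 <- runif(1, 0, 1.5)
    l2 <- runif(1, 0, 1)
    g <- runif(1, 1.5, 8)
    if (g * (1 + l2) <= 1) next
    grid <- seq(-6, 6, length.out = 240001)
    mcp <- ifelse(abs(grid) <= g * l1,
      l1 * abs(grid) - grid^2 / (2 * g), g * l1^2 / 2
    )
    obj <- 0.5 * (z - grid)^2 + mcp + 0.5 * l2 * grid^2
    expect_equal(mnet_threshold(z, l1, l2, g), grid[which.min(obj)],
      tolerance = 1e-4
    )
  }
})

test_that("a non-convex subproblem is refused", {
  expect_error(mnet_threshold(1, 0.5, 0, 0.9), "Non-convex")
  expect_error(fit_mnet(matrix(rnorm(20), 10), rnorm(10),
    lambda = 1, alpha = 1, gamma = 0.9
  ), "gamma")
})

test_that("lambda = 0 reproduces ordinary least squares", {
  set.seed(2)
  x <- matrix(rnorm(30 * 3), 30, 3)
  z <- cbind(age = rnorm(30), bmi = rnorm(30))
  y <- x %*% c(1, -2, 0.5) + z %*% c(0.3, -0.4) + rnorm(30, sd = 0.3)
  fit <- fit_mnet(x, y, covariates = z, lambda = 0, alpha = 0.5, gamma = 3)
  ref <- coef(lm(y ~ z + x))
  expect_equal(unname(fit$beta), unname(ref[4:6]), tolerance = 1e-6)
  expect_equal(unname(fit$covariate_coef), unname(ref[2:3]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ref[1]), tolerance = 1e-6)
})

test_that("a huge gamma with alpha = 1 reduces to the LASSO", {
  set.seed(3)
  x <- matrix(rnorm(20 * 5), 20, 5)
  y <- x %*% c(2, 0, -1, 0, 0) + rnorm(20, sd = 0.5)
  lam <- 0.3
  fit <- fit_mnet(x, y, lambda = lam, alpha = 1, gamma = 1e8, tol = 1e-10)
  ref <- glmnet::glmnet(x, y,
    alpha = 1, lambda = lam, standardize = TRUE,
    intercept = TRUE, thresh = 1e-14
  )
  expect_equal(unname(fit$beta), as.numeric(ref$beta), tolerance = 1e-4)
  expect_equal(fit$intercept, as.numeric(ref$a0), tolerance = 1e-4)
})

test_that("total shrinkage zeroes the penalized block and keeps covariate OLS", {
  set.seed(4)
  x <- matrix(rnorm(40 * 4), 40, 4)
  z <- cbind(age = rnorm(40))
  y <- z[, 1] * 2 + rnorm(40)
  fit <- fit_mnet(x, y, covariates = z, lambda = 50, alpha = 0.9, gamma = 3)
  expect_true(all(fit$beta == 0))
  ref <- coef(lm(y ~ z))
  expect_equal(unname(fit$covariate_coef), unname(ref[2]), tolerance = 1e-6)
})

test_that("the penalized objective never increases across sweeps", {
  set.seed(5)
  x <- matrix(rnorm(30 * 6), 30, 6)
  y <- rnorm(30)
  # debug mode asserts monotone objective internally
  expect_no_error(
    fit_mnet(x, y, lambda = 0.4, alpha = 0.7, gamma = 2.5, debug = TRUE)
  )
})

test_that("fitted coefficients reach the global minimum on small instances", {
  set.seed(6)
  for (i in 1:5) {
    n <- sample(15:30, 1)
    p <- sample(2:4, 1)
    x <- matrix(rnorm(n * p), n, p)
    beta_true <- sample(c(-2, 0, 1.5), p, replace = TRUE)
    y <- as.numeric(x %*% beta_true + rnorm(n, sd = 0.5))
    lam <- runif(1, 0.05, 0.6)
    a <- runif(1, 0.3, 0.9)
    g <- sample(c(2.5, 3, 8), 1)
    fit <- fit_mnet(x, y, lambda = lam, alpha = a, gamma = g, tol = 1e-9)

    cm <- colMeans(x)
    cs <- sqrt(colMeans(x^2) - cm^2)
    xs <- sweep(sweep(x, 2, cm, "-"), 2, cs, "/")
    yc <- y - mean(y)
    zc <- matrix(numeric(0), n, 0)
    starts <- list(
      rep(0, p), unname(fit$beta_std),
      unname(fit$beta_std) + rnorm(p, sd = 0.05)
    )
    opt <- oracle_mnet_minimize(xs, zc, yc, a * lam, (1 - a) * lam, g, starts)
    obj_fit <- oracle_mnet_objective(
      unname(fit$beta_std), numeric(0), xs, zc, yc, a * lam, (1 - a) * lam, g
    )
    expect_lte(obj_fit, opt$value + 1e-8)
    expect_equal(unname(fit$beta_std), opt$par, tolerance = 1e-3)
  }
})

test_that("warm-started path solutions match cold starts", {
  set.seed(7)
  x <- matrix(rnorm(40 * 8), 40, 8)
  y <- x %*% c(2, -2, rep(0, 6)) + rnorm(40, sd = 0.5)
  lams <- c(1, 0.5, 0.2, 0.05)
  cv <- cv_mnet(x, y, lambda = lams, alpha = 0.5, gamma = 3, n_folds = 4, seed = 1)
  for (l in lams) {
    cold <- fit_mnet(x, y, lambda = l, alpha = 0.5, gamma = 3, tol = 1e-9)
    # the CV refit at the chosen lambda used warm starts along the path
    if (abs(l - cv$best$lambda) < 1e-12) {
      expect_equal(cv$fit$beta, cold$beta, tolerance = 1e-6)
    }
  }
})

test_that("cross-validation recovers planted features and prunes noise", {
  set.seed(8)
  n <- 100
  p <- 20
  x <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(x[, 1:3] %*% c(3, -3, 2.5)) + rnorm(n, sd = 0.5)
  cv <- cv_mnet(x, y,
    alpha = c(0.5, 0.9), gamma = 3, nlambda = 30,
    n_folds = 5, seed = 2
  )
  picked <- which(cv$fit$beta != 0)
  expect_true(all(1:3 %in% picked))
  expect_identical(nrow(cv$surface), 60L) # |lambda| x |alpha| x |gamma|

  ynull <- rnorm(n)
  cvn <- cv_mnet(x, ynull,
    alpha = 0.5, gamma = 3, nlambda = 30,
    n_folds = 5, seed = 3
  )
  expect_lte(sum(cvn$fit$beta != 0), 4)
})

test_that("CV ties break toward the sparser (larger lambda) model", {
  set.seed(9)
  x <- matrix(rnorm(30 * 2), 30, 2)
  y <- rnorm(30)
  # duplicate lambda values force exact ties in the surface
  cv <- cv_mnet(x, y, lambda = c(5, 5, 1), alpha = 0.5, gamma = 3,
                n_folds = 3, seed = 1)
  dup <- cv$surface[cv$surface$lambda == 5, ]
  expect_equal(dup$mse[1], dup$mse[2], tolerance = 1e-12)
  if (min(dup$mse) <= min(cv$surface$mse) + 1e-12) {
    expect_equal(cv$best$lambda, 5)
  }
})
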