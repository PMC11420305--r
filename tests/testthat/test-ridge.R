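# Ridge-penalized logistic regression, LOOCV index, AROC, penalty choice.

test_that("infinite shrinkage collapses slopes and predictions to prevalence", {
  set.seed(1)
  X <- matrix(rnorm(200 * 5), 200)
  y <- rbinom(200, 1, 0.4)
  fit <- fit_ridge_logistic(X, y, lambda = 1e9)
  expect_lt(max(abs(fit$beta)), 1e-4)
  expect_lt(max(abs(predict_index(fit, X) - mean(y))), 1e-4)
})

test_that("the fit matches exhaustive grid maximization of the objective", {
  set.seed(2)
  X <- matrix(rnorm(16), 8, 2)
  y <- rep(c(0, 1), 4)
  fit <- fit_ridge_logistic(X, y, lambda = 1, standardize = FALSE,
                            intercept = FALSE)
  best <- grid_oracle(X, y, lambda = 1)
  expect_lt(max(abs(fit$beta - best)), 2e-3)
  # gradient vanishes at the solution
  eta <- drop(X %*% fit$beta)
  g <- drop(crossprod(X, y - plogis(eta))) - 2 * fit$beta
  expect_lt(sqrt(sum(g^2)), 1e-8)
})

test_that("duplicating every row while doubling lambda leaves beta unchanged", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  f1 <- fit_ridge_logistic(X, y, lambda = 2, standardize = FALSE)
  f2 <- fit_ridge_logistic(rbind(X, X), c(y, y), lambda = 4,
                           standardize = FALSE)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-7)
})

test_that("the fit agrees with an independent coordinate-descent solver", {
  library(glmnet)
  set.seed(4)
  n <- 300; p <- 8
  X <- matrix(rnorm(n * p), n)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  lambda <- 3
  fit <- fit_ridge_logistic(X, y, lambda, standardize = FALSE)
  # glmnet minimizes (1/n) negloglik + (lambda_g/2) ||beta||^2 at alpha=0,
  # so lambda_g = 2 * lambda / n reproduces the same maximizer
  g <- glmnet(X, y, family = "binomial", alpha = 0,
              lambda = 2 * lambda / n, standardize = FALSE,
              thresh = 1e-14)
  expect_equal(unname(fit$beta), as.numeric(g$beta), tolerance = 1e-4)
  expect_equal(fit$intercept, as.numeric(g$a0), tolerance = 1e-4)
})

test_that("objective at the solution dominates random perturbations", {
  set.seed(5)
  X <- matrix(rnorm(50 * 4), 50)
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  fit <- fit_ridge_logistic(X, y, lambda = 1.5, standardize = FALSE,
                            intercept = FALSE)
  f0 <- ridge_objective(X, y, fit$beta, 0, 1.5)
  for (k in 1:1000) {
    d <- rnorm(4); d <- d / sqrt(sum(d^2)) * 1e-2
    expect_lte(ridge_objective(X, y, fit$beta + d, 0, 1.5), f0)
  }
})

test_that("coefficient norm shrinks monotonically in lambda", {
  set.seed(6)
  grid <- 10^seq(-2, 3, length.out = 10)
  for (k in 1:20) {
    n <- 60; p <- 6
    X <- matrix(rnorm(n * p), n)
    y <- rbinom(n, 1, plogis(X %*% rnorm(p, sd = 0.5)))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    norms <- vapply(grid, function(l)
      sqrt(sum(fit_ridge_logistic(X, y, l)$beta^2)), numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("predict_index is the logistic inverse link", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  y <- rep(c(0, 1), 5)
  fit <- fit_ridge_logistic(X, y, lambda = 1)
  x <- X[4, ]
  z <- sum((x - fit$standardization$mean) / fit$standardization$sd *
             fit$beta) + fit$intercept
  expect_equal(predict_index(fit, x), 1 / (1 + exp(-z)), tolerance = 1e-12)
  # at the standardized origin with a zero intercept the index is 1/2
  fit0 <- fit
  fit0$intercept <- 0
  expect_equal(predict_index(fit0, fit$standardization$mean), 0.5)
  # saturation
  fit0$intercept <- 40
  expect_equal(predict_index(fit0, fit$standardization$mean), 1,
               tolerance = 1e-12)
  expect_error(predict_index(fit, c(1, NA, 2)), "missing")
})

test_that("AROC equals the pairwise win fraction, ties counted one half", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(8)
  for (k in 1:10) {
    scores <- sample(1:8, 50, replace = TRUE)   # heavy ties
    labels <- rbinom(50, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    brute <- sum(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(auroc(scores, labels),
                 brute / (length(pos) * length(neg)), tolerance = 0)
  }
  expect_error(auroc(1:4, rep(1, 4)), "degenerate")
})

test_that("LOOCV produces one leakage-free prediction per subject", {
  sim <- small_cohort(n = 40, seed = 12)
  y <- as.integer(sim$subjects$sex == "female")
  res <- loocv_index(sim$features, y, lambda = 10)
  expect_equal(res$n_fits, 40L)
  expect_equal(nrow(res$index), 40L)
  expect_true(all(res$index$fundus_sex_index > 0 &
                    res$index$fundus_sex_index < 1))
  # permuting the held-out subject's own label cannot change its prediction
  y2 <- y; y2[17] <- 1 - y2[17]
  res2 <- loocv_index(sim$features, y2, lambda = 10)
  expect_equal(res$index$fundus_sex_index[17],
               res2$index$fundus_sex_index[17], tolerance = 1e-9)
})

test_that("lambda selection behaves on degenerate and informative inputs", {
  sim <- small_cohort(n = 80, seed = 13)
  y <- as.integer(sim$subjects$sex == "female")
  expect_error(select_lambda(sim$features, y, grid = numeric(0)), "empty")
  expect_equal(as.numeric(select_lambda(sim$features, y, grid = 7)), 7)
  # informative data should tolerate less shrinkage than pure noise
  set.seed(14)
  grid <- 10^seq(-1, 4, length.out = 6)
  pick <- function(X, y) as.numeric(select_lambda(X, y, grid = grid, k = 5))
  sel <- replicate(10, {
    n <- 150; p <- 10
    Xs <- matrix(rnorm(n * p), n)
    ys <- rbinom(n, 1, plogis(Xs %*% rep(0.6, p)))
    if (length(unique(ys)) < 2) ys[1:2] <- c(0, 1)
    Xn <- matrix(rnorm(n * p), n)
    yn <- rbinom(n, 1, 0.5)
    if (length(unique(yn)) < 2) yn[1:2] <- c(0, 1)
    c(signal = pick(Xs, ys), noise = pick(Xn, yn))
  })
  expect_lt(median(sel["signal", ]), median(sel["noise", ]))
})

test_that("single-class labels are refused everywhere", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_ridge_logistic(X, rep(1, 10), 1), "degenerate")
  expect_error(loocv_index(X, rep(0, 10), 1), "degenerate")
})
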