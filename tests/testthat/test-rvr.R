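# Independent evidence evaluation for a shared alpha: the log marginal
# likelihood of y under C = sigma2 I + (1/alpha) Phi Phi', computed from the
# dense covariance directly (no reuse of the package's internals).
oracle_evidence <- function(X, y, alpha, sigma2) {
  Phi <- cbind(tcrossprod(X), 1)
  C <- sigma2 * diag(length(y)) + tcrossprod(Phi) / alpha
  -0.5 * (length(y) * log(2 * pi) +
            determinant(C, logarithm = TRUE)$modulus +
            drop(crossprod(y, solve(C, y))))
}

test_that("constant targets give a bias-only model", {
  set.seed(1)
  X <- matrix(rnorm(30), 10)
  m <- fit_rvr(X, rep(4, 10))
  expect_length(m$relevance_indices, 0)
  expect_equal(predict(m, matrix(rnorm(15), 5)), rep(4, 5))
  expect_equal(back_project_weights(m)$weight, rep(0, 3))
})

test_that("noiseless linear targets are recovered to least-squares accuracy", {
  set.seed(2)
  X <- matrix(rnorm(30 * 5), 30)
  y <- 3 * X[, 1]
  m <- fit_rvr(X, y)
  pred <- predict(m, X)
  ls_pred <- fitted(lm(y ~ X))  # exact oracle: y is in the column span
  expect_gt(cor(pred, y), 0.999)
  expect_lt(max(abs(pred - ls_pred)), 1e-3)
  w <- back_project_weights(m)
  expect_equal(which.max(abs(w$weight)), 1L)
  expect_equal(w$weight[1], 3, tolerance = 1e-3)
})

test_that("fitted evidence attains the shared-alpha grid-search maximum", {
  set.seed(3)
  X <- matrix(rnorm(5 * 2), 5)
  y <- X[, 1] + rnorm(5, 0, 0.3)
  m <- fit_rvr(X, y)
  grid <- expand.grid(la = seq(-6, 8, by = 0.1),
                      ls = seq(-6, 2, by = 0.1))
  ev <- mapply(function(la, ls) oracle_evidence(X, y, exp(la), exp(ls)),
               grid$la, grid$ls)
  # per-sample alphas can only improve on the best shared alpha
  expect_gte(m$log_evidence, max(ev) - 1e-6)
})

test_that("the ridge limit matches closed-form kernel ridge exactly", {
  set.seed(4)
  X <- matrix(rnorm(15 * 4), 15)
  y <- X[, 2] - 0.5 * X[, 4] + rnorm(15, 0, 0.2)
  a <- 2.5; s2 <- 0.3
  m <- fit_rvr(X, y, fixed_alpha = a, fixed_sigma2 = s2)
  Phi <- cbind(tcrossprod(X), 1)
  mu <- solve(crossprod(Phi) + s2 * a * diag(ncol(Phi)), crossprod(Phi, y))
  Xt <- matrix(rnorm(8 * 4), 8)
  Phit <- cbind(tcrossprod(Xt, X), 1)
  expect_equal(predict(m, Xt), drop(Phit %*% mu), tolerance = 1e-8)
})

test_that("log evidence is non-decreasing across update iterations", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 25
    X <- matrix(rnorm(n * 6), n)
    y <- X[, 1] - X[, 3] + rnorm(n, 0, 0.5)
    m <- fit_rvr(X, y)
    expect_true(all(diff(m$evidence) > -1e-8),
                info = paste("seed", seed))
  }
})

test_that("pure-noise targets yield sparse models", {
  sparse <- vapply(1:20, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(100 * 10), 100)
    y <- rnorm(100)
    m <- fit_rvr(X, y)
    length(m$relevance_indices) < 100
  }, logical(1))
  expect_gte(mean(sparse), 0.95)
})

test_that("predictions and weights scale with the target", {
  set.seed(6)
  X <- minmax_scale_fold(matrix(rnorm(20 * 4), 20))$train
  y <- X[, 1] + rnorm(20, 0, 0.3)
  cc <- 10
  m1 <- fit_rvr(X, y)
  m2 <- fit_rvr(X, cc * y)
  Xt <- matrix(runif(10 * 4), 10)
  expect_equal(predict(m2, Xt), cc * predict(m1, Xt), tolerance = 1e-6)
  expect_equal(back_project_weights(m2)$weight,
               cc * back_project_weights(m1)$weight, tolerance = 1e-6)
  expect_equal(m2$bias, cc * m1$bias, tolerance = 1e-6)
})

test_that("kernel-form predictions equal the back-projected linear form", {
  set.seed(7)
  for (case in 1:3) {
    n <- c(12, 25, 40)[case]
    p <- c(3, 8, 15)[case]
    X <- matrix(rnorm(n * p), n)
    y <- X %*% rnorm(p) + rnorm(n, 0, 0.4)
    m <- fit_rvr(X, y)
    w <- back_project_weights(m)$weight
    Xt <- matrix(rnorm(100 * p), 100)
    expect_lt(max(abs(predict(m, Xt) -
                        (drop(Xt %*% w) + m$bias))), 1e-8)
  }
})

test_that("a relevance vector of an interpolating model predicts its own y", {
  set.seed(8)
  X <- matrix(rnorm(20 * 3), 20)
  y <- drop(X %*% c(2, -1, 0.5))  # noiseless, interpolable
  m <- fit_rvr(X, y)
  rel <- m$relevance_indices
  expect_gt(length(rel), 0)
  expect_equal(predict(m, X[rel, , drop = FALSE]), y[rel],
               tolerance = 1e-4)
})

test_that("an all-zero feature column receives zero weight", {
  set.seed(9)
  X <- matrix(rnorm(20 * 4), 20)
  X[, 3] <- 0
  y <- X[, 1] + rnorm(20, 0, 0.2)
  m <- fit_rvr(X, y)
  expect_equal(back_project_weights(m)$weight[3], 0)
})

test_that("back-projection is the weighted sum of relevance vectors", {
  fake <- structure(
    list(relevance_indices = 1L, sample_weights = 2,
         bias = 0, X_train = matrix(c(1, 0, -1), 1, 3,
                                    dimnames = list(NULL, c("a", "b", "c"))),
         alphas = c(1, 1e12), noise_variance = 1, kernel = "linear"),
    class = "rvr"
  )
  expect_equal(back_project_weights(fake)$weight, c(2, 0, -2))
})

test_that("dimension mismatches and malformed inputs fail loudly", {
  set.seed(10)
  X <- matrix(rnorm(30), 10)
  m <- fit_rvr(X, rnorm(10))
  expect_error(predict(m, matrix(rnorm(8), 2)), "dimension mismatch")
  expect_error(fit_rvr(X[1:2, ], rnorm(2)), "3 training samples")
  expect_error(fit_rvr(X, rnorm(9)), "length")
})

test_that("JSON round-trip preserves predictions", {
  set.seed(11)
  X <- matrix(rnorm(15 * 3), 15)
  y <- X[, 1] + rnorm(15, 0, 0.3)
  m <- fit_rvr(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_rvr_json(m, path)
  m2 <- read_rvr_json(path)
  Xt <- matrix(rnorm(20 * 3), 20)
  expect_equal(predict(m2, Xt), predict(m, Xt), tolerance = 1e-10)
  expect_equal(m2$noise_variance, m$noise_variance)
})

test_that("tidy and glance expose weights and fit summary", {
  set.seed(12)
  X <- matrix(rnorm(20 * 3), 20)
  colnames(X) <- c("u", "v", "w")
  y <- X[, 1] + rnorm(20, 0, 0.3)
  m <- fit_rvr(X, y)
  td <- tidy(m)
  expect_identical(td$term, c("u", "v", "w"))
  expect_equal(td$estimate, back_project_weights(m)$weight)
  gl <- glance(m)
  expect_equal(gl$n_samples, 20)
  expect_true(gl$n_relevance <= 20)
})
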