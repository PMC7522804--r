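test_that("accuracy metrics behave on degenerate and shifted predictions", {
  y <- c(3, 7, 11, 5, 9, 13, 4, 8)
  acc <- prediction_accuracy(y, y)
  expect_equal(acc$r, 1)
  expect_equal(acc$partial_r, 1)
  expect_equal(acc$mae, 0)

  acc2 <- prediction_accuracy(y, y + 2)
  expect_equal(acc2$r, 1)
  expect_equal(acc2$mae, 2)
})

test_that("partial correlation matches the single-covariate recursion", {
  set.seed(3)
  n <- 12
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + rnorm(n)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  acc <- prediction_accuracy(x, y, matrix(z, ncol = 1))
  expect_equal(acc$partial_r, oracle, tolerance = 1e-12)
})

test_that("LOOCV recovers an oracle feature almost perfectly", {
  y <- rnorm(20, 18, 2.5)
  ph <- make_phenotypes(y)
  feats <- oracle_feature_table(ph$psqi, ph$subject)
  cv <- run_loocv(feats, ph)
  expect_gt(cv$metrics$r, 0.99)
  expect_lt(cv$metrics$mae, 0.5)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(glance(cv)$n, 20)
})

test_that("LOOCV fold bookkeeping tests each subject exactly once", {
  y <- rnorm(6, 18, 2)
  ph <- make_phenotypes(y, seed = 2)
  feats <- oracle_feature_table(ph$psqi, ph$subject, seed = 3)
  cv <- run_loocv(feats, ph)
  pr <- cv$predictions
  expect_identical(pr$subject, ph$subject)
  expect_identical(pr$fold, 1:6)  # subject i is the test set of fold i
  expect_identical(pr$observed, as.numeric(ph$psqi))
  expect_true(all(table(pr$subject) == 1))
})

test_that("k-fold with k = n reproduces LOOCV fold for fold", {
  y <- rnorm(12, 18, 2.5)
  ph <- make_phenotypes(y, seed = 4)
  feats <- oracle_feature_table(ph$psqi, ph$subject, seed = 5)
  loo <- run_loocv(feats, ph)
  kf <- run_repeated_kfold(feats, ph, k = 12L, repeats = 1L, seed = 99)
  m <- merge(loo$predictions[, c("subject", "predicted")],
             kf$predictions[, c("subject", "predicted")], by = "subject")
  expect_equal(m$predicted.x, m$predicted.y, tolerance = 1e-12)
})

test_that("repeated k-fold is deterministic in (seed, repeat) and averages
           per-repeat metrics", {
  y <- rnorm(23, 18, 2.5)
  ph <- make_phenotypes(y, seed = 6)
  feats <- oracle_feature_table(ph$psqi, ph$subject, seed = 7)
  a <- run_repeated_kfold(feats, ph, k = 10L, repeats = 3L, seed = 5)
  b <- run_repeated_kfold(feats, ph, k = 10L, repeats = 3L, seed = 5)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$predictions, b$predictions)

  # reported metrics are means of the per-repeat metrics
  expect_equal(a$metrics$r, mean(a$metrics_by_repeat$r))
  expect_equal(a$metrics$mae, mean(a$metrics_by_repeat$mae))

  # non-divisible n: the first n %% k folds take the extra subject
  sizes <- table(a$predictions$fold[a$predictions$rep == 1])
  expect_equal(unname(as.integer(sizes)), c(3, 3, 3, rep(2, 7)))

  expect_error(run_repeated_kfold(feats, ph, k = 30L, seed = 1), "exceeds")
})

test_that("poisoning held-out rows before training changes nothing", {
  y <- rnorm(10, 18, 2.5)
  ph <- make_phenotypes(y, seed = 8)
  feats <- oracle_feature_table(ph$psqi, ph$subject, p_noise = 4, seed = 9)
  X <- connpredict:::.feature_matrix(feats, ph$subject)

  # LOOCV folds
  folds <- as.list(seq_len(10))
  clean <- connpredict:::.make_fold_caches(X, folds)
  spied <- connpredict:::.make_fold_caches(X, folds, poison = TRUE)
  expect_identical(connpredict:::.cv_predict(clean, y)$pred,
                   connpredict:::.cv_predict(spied, y)$pred)

  # k-fold folds
  folds_k <- connpredict:::.kfold_partition(10, 3, 42)
  clean_k <- connpredict:::.make_fold_caches(X, folds_k)
  spied_k <- connpredict:::.make_fold_caches(X, folds_k, poison = TRUE)
  expect_identical(connpredict:::.cv_predict(clean_k, y)$pred,
                   connpredict:::.cv_predict(spied_k, y)$pred)
})

test_that("covariate handling normalises sex and rejects missing columns", {
  y <- rnorm(12, 18, 2)
  ph <- make_phenotypes(y, seed = 10)
  feats <- oracle_feature_table(ph$psqi, ph$subject, seed = 11)
  expect_error(run_loocv(feats, ph, covariates = c("age", "income")),
               "income")

  ph2 <- ph
  ph2$sex <- ifelse(ph$sex == "F", 1, 0)  # numeric coding accepted
  cv1 <- run_loocv(feats, ph)
  cv2 <- run_loocv(feats, ph2)
  expect_equal(cv1$metrics$partial_r, cv2$metrics$partial_r)

  ph3 <- ph
  ph3$sex[1] <- "X"
  expect_error(run_loocv(feats, ph3), "M, F, 0, 1")
})

test_that("subject-id mismatches between tables are reported", {
  y <- rnorm(8, 18, 2)
  ph <- make_phenotypes(y, seed = 12)
  feats <- oracle_feature_table(ph$psqi, ph$subject, seed = 13)
  feats$subject[1] <- "ghost"
  expect_error(run_loocv(feats, ph), "ghost")
})

test_that("too few subjects for the covariate set is an error", {
  y <- c(1, 2, 3, 4, 5)
  Z <- matrix(rnorm(10), 5, 2)
  expect_error(prediction_accuracy(y, y + 1, cbind(Z, Z[, 1] + Z[, 2],
                                                   rnorm(5))),
               "degrees of freedom")
})
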