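test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- cohort_config(n_subjects = 8, n_regions = 12, planted_regions = 1:2,
                       effect_size = 0.8, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$connectomes, b$connectomes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
})

test_that("every simulated connectome is a valid correlation matrix", {
  ch <- small_cohort(n = 10, R = 25, planted = 1:4, effect = 1.5,
                     noise = 0.08, seed = 5)
  for (C in ch$connectomes) {
    expect_lt(max(abs(C - t(C))), 1e-12)
    expect_equal(unname(diag(C)), rep(1, 25))
    expect_lte(max(abs(C)), 1)
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  expect_identical(names(ch$connectomes), ch$phenotypes$subject)
})

test_that("score moments match the rounded-truncated-normal oracle", {
  # oracle: integer bins k in [0, 21] with end bins absorbing the tails
  mu <- 18.4; sig <- 2.3
  k <- 0:21
  upper <- pnorm((k + 0.5 - mu) / sig)
  upper[22] <- 1
  lower <- c(0, upper[-22])
  pk <- upper - lower
  o_mean <- sum(k * pk)
  o_sd <- sqrt(sum(k^2 * pk) - o_mean^2)

  ch <- simulate_cohort(cohort_config(n_subjects = 10000, n_regions = 3,
                                      score_mean = mu, score_sd = sig,
                                      seed = 9))
  expect_lt(abs(mean(ch$phenotypes$psqi) - o_mean), 0.02 * o_mean)
  expect_lt(abs(sd(ch$phenotypes$psqi) - o_sd), 0.02 * o_sd)
  expect_true(all(ch$phenotypes$psqi >= 0 & ch$phenotypes$psqi <= 21))
})

test_that("effect_size = 0 leaves connectivity independent of the score", {
  ch <- simulate_cohort(cohort_config(n_subjects = 200, n_regions = 20,
                                      planted_regions = 1:3, effect_size = 0,
                                      seed = 31))
  y <- ch$phenotypes$psqi
  pe <- ch$truth$planted_edges
  rs <- ps <- numeric(nrow(pe))
  for (e in seq_len(nrow(pe))) {
    v <- vapply(ch$connectomes, function(C) C[pe$pos_i[e], pe$pos_j[e]],
                numeric(1))
    ct <- cor.test(v, y)
    rs[e] <- ct$estimate
    ps[e] <- ct$p.value
  }
  expect_lt(abs(mean(rs)), 0.03)
  expect_lt(mean(ps < 0.05), 0.15)  # nominal false-positive rate ~5%
})

test_that("planted-edge score coupling matches a brute-force oracle", {
  R <- 20; planted <- 1:3; effect <- 0.5; noise <- 0.05
  # independent re-implementation of the generative equations at large n,
  # tracking one representative planted edge (1,2) and one null edge (10,11)
  oracle_edge_cor <- function(n, seed) {
    set.seed(seed)
    sys_block <- sort(rep_len(1:7, R))
    base <- ifelse(outer(sys_block, sys_block, `==`), 0.3, 0.05)
    diag(base) <- 1
    pl <- rep(FALSE, R); pl[planted] <- TRUE
    inc <- outer(pl, pl, `|`); diag(inc) <- FALSE
    y <- pmin(pmax(round(rnorm(n, 18.4, 2.3)), 0), 21)
    z <- (y - mean(y)) / sd(y)
    v12 <- v1011 <- numeric(n)
    up <- upper.tri(base)
    for (i in seq_len(n)) {
      E <- matrix(0, R, R)
      E[up] <- rnorm(sum(up), 0, noise)
      E <- E + t(E)
      M <- base + E
      M[inc] <- M[inc] + effect * 0.05 * z[i]
      M <- pmin(pmax(M, -0.999), 0.999); diag(M) <- 1
      ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
      if (min(ev$values) < 1e-8) {
        vals <- pmax(ev$values, 1e-8)
        M <- ev$vectors %*% (vals * t(ev$vectors))
        M <- M / tcrossprod(sqrt(diag(M)))
      }
      v12[i] <- M[1, 2]
      v1011[i] <- M[10, 11]
    }
    c(planted = cor(v12, y), null = cor(v1011, y))
  }
  truth <- oracle_edge_cor(20000, seed = 1)

  ch <- simulate_cohort(cohort_config(n_subjects = 200, n_regions = R,
                                      planted_regions = planted,
                                      effect_size = effect, noise_sd = noise,
                                      seed = 77))
  y <- ch$phenotypes$psqi
  v12 <- vapply(ch$connectomes, function(C) C[1, 2], numeric(1))
  v1011 <- vapply(ch$connectomes, function(C) C[10, 11], numeric(1))
  mc_tol <- 3 / sqrt(200)  # ~3 SE of a correlation estimate at n = 200
  expect_lt(abs(cor(v12, y) - truth["planted"]), mc_tol)
  expect_lt(abs(cor(v1011, y) - truth["null"]), mc_tol)
  expect_gt(truth["planted"], 0.3)  # the planted coupling is real
})

test_that("planted signal is recoverable by OLS at high effect size", {
  ch <- small_cohort(n = 100, R = 20, planted = 1:3, effect = 2,
                     noise = 0.01, seed = 13)
  pe <- ch$truth$planted_edges
  V <- vapply(ch$connectomes,
              function(C) C[cbind(pe$pos_i, pe$pos_j)],
              numeric(nrow(pe)))
  fit <- lm(ch$phenotypes$psqi ~ t(V))
  expect_gt(cor(fitted(fit), ch$phenotypes$psqi), 0.9)
})

test_that("simulated time series reproduce the target correlations", {
  # identity target: all off-diagonal empirical correlations near zero
  ch <- simulate_cohort(cohort_config(n_subjects = 5, n_regions = 4,
                                      noise_sd = 0, seed = 3,
                                      base_within = 0, base_between = 0))
  ch$connectomes <- lapply(ch$connectomes, function(C) {
    diag(nrow(C)) + 0 * C
  })
  ch <- simulate_timeseries(ch, n_timepoints = 100000, seed = 4)
  C_emp <- compute_connectivity(ch$timeseries[[1]])
  expect_lt(max(abs(C_emp[upper.tri(C_emp)])), 0.02)

  # forced pair: r12 = 0.8, other pairs 0
  target <- diag(3)
  target[1, 2] <- target[2, 1] <- 0.8
  ids <- c("R001", "R002", "R003")
  dimnames(target) <- list(ids, ids)
  ch$connectomes <- list(S001 = target)
  ch$phenotypes <- ch$phenotypes[1, ]
  ch <- simulate_timeseries(ch, n_timepoints = 50000, seed = 5)
  C_emp <- compute_connectivity(ch$timeseries$S001)
  expect_lt(abs(C_emp[1, 2] - 0.8), 0.02)
})

test_that("empirical correlation spread follows Fisher-z sampling variance", {
  # many subjects share the same 5-region target; the spread of atanh(r)
  # across subjects should match 1/sqrt(T - 3)
  Tlen <- 200
  ch <- simulate_cohort(cohort_config(n_subjects = 150, n_regions = 5,
                                      noise_sd = 0, seed = 21))
  ch <- simulate_timeseries(ch, n_timepoints = Tlen, seed = 22)
  z12 <- vapply(ch$timeseries,
                function(ts) atanh(cor(ts[, 1], ts[, 2])), numeric(1))
  expect_lt(abs(sd(z12) - 1 / sqrt(Tlen - 3)), 0.2 / sqrt(Tlen - 3))
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(n_subjects = 4, seed = 1), "n_subjects")
  expect_error(cohort_config(n_subjects = 10, n_regions = 2, seed = 1),
               "n_regions")
  expect_error(cohort_config(n_subjects = 10, n_regions = 10,
                             planted_regions = c(1, 11), seed = 1),
               "planted_regions")
  expect_error(cohort_config(n_subjects = 10, seed = 1,
                             planted_regions = c(2, 2)), "planted_regions")
})

test_that("non-finite perturbations fail with the subject named", {
  expect_error(repair_correlation_matrix(matrix(c(1, NaN, NaN, 1), 2)),
               "non-finite")
})
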