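# Shared fixtures, all generated in code.

# Random valid correlation matrix with region-id dimnames.
make_valid_corr <- function(R, seed) {
  set.seed(seed)
  A <- matrix(rnorm(R * (R + 5)), R + 5, R)
  C <- cov2cor(crossprod(A))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  ids <- sprintf("R%03d", seq_len(R))
  dimnames(C) <- list(ids, ids)
  C
}

# Small planted-signal cohort used across modules.
small_cohort <- function(n = 20, R = 20, planted = 1:3, effect = 1,
                         noise = 0.05, seed = 101) {
  simulate_cohort(cohort_config(
    n_subjects = n, n_regions = R, planted_regions = planted,
    effect_size = effect, noise_sd = noise, seed = seed
  ))
}

# Feature table whose first column is an almost-noiseless copy of the score
# (the "oracle feature"), padded with pure-noise columns.
oracle_feature_table <- function(y, subjects, p_noise = 3, seed = 7,
                                 noise = 1e-3) {
  set.seed(seed)
  X <- cbind(y + rnorm(length(y), 0, noise),
             matrix(rnorm(length(y) * p_noise), length(y)))
  colnames(X) <- c("oracle", sprintf("noise%d", seq_len(p_noise)))
  dplyr::bind_cols(tibble::tibble(subject = subjects),
                   tibble::as_tibble(X))
}

# Phenotype table for hand-built feature matrices.
make_phenotypes <- function(y, seed = 11) {
  n <- length(y)
  set.seed(seed)
  tibble::tibble(
    subject = sprintf("S%03d", seq_len(n)),
    psqi = as.integer(pmin(pmax(round(y), 0), 21)),
    age = rnorm(n, 35, 8),
    sex = ifelse(rbinom(n, 1, 0.5) == 1, "F", "M"),
    education = round(rnorm(n, 12, 3)),
    ess = round(pmin(pmax(rnorm(n, 9, 4), 0), 24)),
    motion = abs(rnorm(n, 0.08, 0.03))
  )
}
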