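#' Configure a synthetic connectome cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' defaults emulate a chronic-insomnia-like cohort: a PSQI-like score with
#' mean 18.4 and SD 2.3 on the 0--21 instrument range, 246 atlas regions
#' grouped into the seven canonical cognitive systems, and demographic
#' covariates (age, sex, education, daytime sleepiness, head motion) drawn
#' independently of the score.
#'
#' The generative model: each subject's score is drawn from a normal
#' distribution, rounded to the integer instrument range; a block-structured
#' base correlation matrix (within-system r = `base_within`, between-system
#' r = `base_between`) is perturbed per subject by independent Gaussian edge
#' noise everywhere and, on edges incident to `planted_regions`, by an
#' additive shift `effect_size * signal_scale * z(score)`; the perturbed
#' matrix is projected back to a valid correlation matrix.
#'
#' @param n_subjects Number of subjects (>= 5).
#' @param n_regions Number of atlas regions (default 246).
#' @param n_timepoints Time points for optional time-series simulation
#'   (default 230, i.e. 240 volumes minus 10 discarded).
#' @param score_mean,score_sd Mean and SD of the latent score (score units).
#' @param score_range Integer instrument range (default `c(0, 21)`).
#' @param planted_regions Integer indices (1-based) of regions carrying
#'   planted signal; may be empty.
#' @param effect_size Dimensionless coupling between the cohort z-score of
#'   the subject's score and the connectivity of planted edges: each planted
#'   edge is shifted by `effect_size * signal_scale * z(score)`.
#' @param noise_sd SD of the independent edge noise (correlation units).
#' @param signal_scale Connectivity-scale amplitude (correlation units) of
#'   one z-unit of score signal at `effect_size = 1`. Default 0.05, a
#'   physiologically plausible connectivity shift; it keeps perturbed edges
#'   inside the valid correlation range so the planted signal survives the
#'   correlation-matrix repair.
#' @param base_within,base_between Base correlation within / between the
#'   seven system blocks.
#' @param covariate_spec Named list of covariate parameters; see defaults.
#' @param seed Integer seed; mandatory, makes the cohort bit-reproducible.
#'
#' @return A `cohort_config` list.
#' @seealso [simulate_cohort()], [simulate_timeseries()]
#' @export
cohort_config <- function(n_subjects,
                          n_regions = 246L,
                          n_timepoints = 230L,
                          score_mean = 18.4,
                          score_sd = 2.3,
                          score_range = c(0L, 21L),
                          planted_regions = integer(),
                          effect_size = 0,
                          noise_sd = 0.05,
                          signal_scale = 0.05,
                          base_within = 0.3,
                          base_between = 0.05,
                          covariate_spec = list(),
                          seed) {
  .assert_scalar_count(n_subjects, "n_subjects", min = 5L)
  .assert_scalar_count(n_regions, "n_regions", min = 3L)
  .assert_scalar_count(n_timepoints, "n_timepoints", min = 3L)
  .assert_scalar_count(seed, "seed", min = 0L)
  stopifnot(score_sd > 0, noise_sd >= 0, is.numeric(effect_size))
  planted_regions <- as.integer(planted_regions)
  if (anyDuplicated(planted_regions) ||
      any(planted_regions < 1L | planted_regions > n_regions)) {
    stop("`planted_regions` must be distinct indices in [1, n_regions]",
         call. = FALSE)
  }
  spec <- utils::modifyList(
    list(age_mean = 38.1, age_sd = 10.3,
         education_mean = 10.2, education_sd = 3.8,
         prop_female = 0.66,
         ess_mean = 9.0, ess_sd = 6.2,
         motion_mean = 0.08, motion_sd = 0.04),
    covariate_spec
  )
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints),
         score_mean = score_mean, score_sd = score_sd,
         score_range = as.integer(score_range),
         planted_regions = planted_regions,
         effect_size = effect_size, noise_sd = noise_sd,
         signal_scale = signal_scale,
         base_within = base_within, base_between = base_between,
         covariate_spec = spec,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Canonical cognitive-system labels used for network aggregation.
.systems <- c("VS", "MT", "DA", "LM", "FP", "DM", "SC")

#' Region metadata table for a synthetic atlas
#'
#' Assigns regions to the seven canonical cognitive systems (visual, motor,
#' dorsal attention, limbic, fronto-parietal, default mode, subcortical) in
#' contiguous near-equal blocks, alternating hemispheres within each block.
#'
#' @param n_regions Number of regions.
#' @return A tibble with columns `region_id`, `name`, `hemisphere`, `system`.
#' @export
make_region_metadata <- function(n_regions) {
  .assert_scalar_count(n_regions, "n_regions", min = 3L)
  idx <- seq_len(n_regions)
  block <- sort(rep_len(seq_along(.systems), n_regions))
  tibble::tibble(
    region_id = sprintf("R%03d", idx),
    name = sprintf("region_%03d", idx),
    hemisphere = ifelse(idx %% 2L == 1L, "L", "R"),
    system = .systems[block]
  )
}

# Block-structured base correlation matrix shared by all subjects.
.base_correlation <- function(n_regions, within, between) {
  block <- sort(rep_len(seq_len(length(.systems)), n_regions))
  same <- outer(block, block, `==`)
  M <- matrix(between, n_regions, n_regions)
  M[same] <- within
  diag(M) <- 1
  M
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Single spectral projection: eigenvalues are clamped at a small positive
#' floor and the result rescaled to unit diagonal, yielding a positive
#' semi-definite matrix with unit diagonal and entries in \[-1, 1\] at the
#' cost of one eigendecomposition. Returns the input untouched when it is
#' already a valid correlation matrix.
#'
#' @param M Symmetric numeric matrix with unit diagonal (approximately).
#' @param eig_floor Smallest retained eigenvalue.
#' @return List with `matrix` (the repaired matrix), `repaired` (logical) and
#'   `frobenius_distance` from the input.
#' @export
repair_correlation_matrix <- function(M, eig_floor = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("`M` must be a square matrix", call. = FALSE)
  }
  if (anyNA(M) || any(!is.finite(M))) {
    stop("matrix contains non-finite entries; no valid correlation matrix ",
         "can be recovered", call. = FALSE)
  }
  M <- (M + t(M)) / 2
  ok <- tryCatch({
    chol(M)
    all(abs(diag(M) - 1) < 1e-12) && max(abs(M)) <= 1
  }, error = function(e) FALSE)
  if (ok) {
    return(list(matrix = M, repaired = FALSE, frobenius_distance = 0))
  }
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  list(matrix = R, repaired = TRUE,
       frobenius_distance = norm(M - R, type = "F"))
}

#' Simulate a cohort of connectomes with a planted connectome-to-score signal
#'
#' Draws per-subject scores, perturbs a common block-structured base
#' correlation matrix with independent edge noise plus a score-coupled shift
#' on edges incident to the planted regions, and repairs each perturbed
#' matrix to a valid correlation matrix. Covariates are drawn independently
#' of the score, so their population correlation with it is zero.
#'
#' @param config A [cohort_config()] object.
#' @return A `synthetic_cohort` list with elements `connectomes` (named list
#'   of region-by-region correlation matrices), `phenotypes` (tibble with
#'   columns `subject`, `psqi`, `age`, `sex`, `education`, `ess`, `motion`),
#'   `regions` (metadata tibble), `truth` (planted regions/edges, effect
#'   size, latent scores) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  R <- config$n_regions
  cs <- config$covariate_spec

  latent <- rnorm(n, config$score_mean, config$score_sd)
  score <- pmin(pmax(round(latent), config$score_range[1]),
                config$score_range[2])
  z <- if (sd(score) > 0) (score - mean(score)) / sd(score) else rep(0, n)

  regions <- make_region_metadata(R)
  base <- .base_correlation(R, config$base_within, config$base_between)
  planted <- config$planted_regions
  incident <- matrix(FALSE, R, R)
  if (length(planted)) {
    pl <- rep(FALSE, R)
    pl[planted] <- TRUE
    incident <- outer(pl, pl, `|`)
    diag(incident) <- FALSE
  }

  subjects <- sprintf("S%03d", seq_len(n))
  upper <- upper.tri(base)
  connectomes <- vector("list", n)
  names(connectomes) <- subjects
  noiseless_edge_shift <- config$effect_size * config$signal_scale * z
  for (i in seq_len(n)) {
    E <- matrix(0, R, R)
    E[upper] <- rnorm(sum(upper), 0, config$noise_sd)
    E <- E + t(E)
    M <- base + E
    if (length(planted)) {
      M[incident] <- M[incident] + noiseless_edge_shift[i]
    }
    M <- pmin(pmax(M, -0.999), 0.999)
    diag(M) <- 1
    rep_out <- tryCatch(
      repair_correlation_matrix(M),
      error = function(e) {
        stop("subject ", subjects[i], ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    Ci <- rep_out$matrix
    dimnames(Ci) <- list(regions$region_id, regions$region_id)
    connectomes[[i]] <- Ci
  }

  sex <- ifelse(rbinom(n, 1L, cs$prop_female) == 1L, "F", "M")
  phenotypes <- tibble::tibble(
    subject = subjects,
    psqi = as.integer(score),
    age = round(rnorm(n, cs$age_mean, cs$age_sd), 1),
    sex = sex,
    education = pmax(round(rnorm(n, cs$education_mean, cs$education_sd)), 0),
    ess = pmin(pmax(round(rnorm(n, cs$ess_mean, cs$ess_sd)), 0), 24),
    motion = round(abs(rnorm(n, cs$motion_mean, cs$motion_sd)), 4)
  )

  planted_edges <- if (length(planted)) {
    map <- .edge_index_map(regions$region_id)
    map[map$pos_i %in% planted | map$pos_j %in% planted, ]
  } else {
    .edge_index_map(regions$region_id)[0, ]
  }

  structure(
    list(connectomes = connectomes,
         timeseries = NULL,
         phenotypes = phenotypes,
         regions = regions,
         truth = list(planted_regions = planted,
                      planted_region_ids = regions$region_id[planted],
                      planted_edges = planted_edges,
                      effect_size = config$effect_size,
                      latent_score = latent,
                      score_z = z),
         config = config),
    class = "synthetic_cohort"
  )
}

#' Simulate regional time series matching each subject's connectome
#'
#' Draws multivariate-normal time series whose population correlation equals
#' the subject's connectome, so that [compute_connectivity()] applied to the
#' output converges to the stored matrix as the number of time points grows.
#' Targets that are not positive semi-definite are repaired first and the
#' Frobenius distance of the repair is reported via `message()`.
#'
#' @param cohort A `synthetic_cohort` (or a named list of correlation
#'   matrices inside one).
#' @param n_timepoints Number of time points per subject.
#' @param seed Integer seed.
#' @return The cohort with a `timeseries` element: a named list of
#'   time-by-region matrices.
#' @export
simulate_timeseries <- function(cohort,
                                n_timepoints = cohort$config$n_timepoints,
                                seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  .assert_scalar_count(n_timepoints, "n_timepoints", min = 3L)
  set.seed(.sub_seed(seed, 0L))
  cohort$timeseries <- lapply(cohort$connectomes, function(C) {
    rep_out <- repair_correlation_matrix(C)
    if (rep_out$repaired) {
      message("target matrix repaired to nearest PSD correlation matrix ",
              "(Frobenius distance ",
              format(rep_out$frobenius_distance, digits = 4), ")")
    }
    ts <- MASS::mvrnorm(n_timepoints, mu = rep(0, ncol(C)),
                        Sigma = rep_out$matrix)
    colnames(ts) <- colnames(C)
    ts
  })
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$config$n_subjects, " subjects, ",
      x$config$n_regions, " regions\n", sep = "")
  cat("  planted regions: ", length(x$truth$planted_regions),
      "; effect size: ", x$truth$effect_size,
      "; seed: ", x$config$seed, "\n", sep = "")
  invisible(x)
}
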