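# Readers/writers for the plain-text interchange formats and the end-to-end
# two-stage study driver.

#' Write a synthetic cohort to plain-text files
#'
#' Writes one tab-delimited region-by-region matrix per subject
#' (`sub-<id>_connectome.tsv`, header row of region ids), a phenotype CSV
#' (`phenotypes.csv`, columns `subject,psqi,age,sex,education,ess,motion`),
#' a region-metadata TSV (`regions.tsv`) and a `truth.json` with the planted
#' indices, effect size and seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$connectomes)) {
    readr::write_tsv(
      tibble::as_tibble(cohort$connectomes[[id]], .name_repair = "minimal"),
      file.path(dir, paste0("sub-", id, "_connectome.tsv"))
    )
  }
  readr::write_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  readr::write_tsv(cohort$regions, file.path(dir, "regions.tsv"))
  jsonlite::write_json(
    list(planted_regions = cohort$truth$planted_regions,
         planted_region_ids = cohort$truth$planted_region_ids,
         effect_size = cohort$truth$effect_size,
         seed = cohort$config$seed,
         n_subjects = cohort$config$n_subjects,
         n_regions = cohort$config$n_regions),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a square connectivity matrix from a delimited text file
#'
#' The delimiter is auto-detected among tab, comma and whitespace; an
#' optional first header row of region ids is detected and used as dimnames.
#'
#' @param path File path.
#' @return Numeric matrix with region-id dimnames.
#' @export
read_connectome <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  tokens <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(tokens)))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) {
    stop("connectome file ", basename(path), " is not square (",
         nrow(M), " x ", ncol(M), ")", call. = FALSE)
  }
  ids <- if (has_header) colnames(M) else sprintf("R%03d", seq_len(ncol(M)))
  dimnames(M) <- list(ids, ids)
  storage.mode(M) <- "double"
  M
}

#' Read all per-subject connectomes from a directory
#'
#' Expects files named `sub-<id>_connectome.tsv` (any delimited text).
#'
#' @param dir Directory containing connectome files.
#' @return Named list of matrices, names = subject ids.
#' @export
read_connectomes <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^sub-.*_connectome\\.",
                           full.names = TRUE))
  if (length(paths) == 0L) {
    stop("no sub-*_connectome files found in ", dir, call. = FALSE)
  }
  ids <- sub("^sub-(.*)_connectome\\..*$", "\\1", basename(paths))
  setNames(lapply(paths, read_connectome), ids)
}

#' Read a phenotype CSV
#'
#' Requires columns `subject` and `psqi`; scores must lie in the 0--21
#' instrument range.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("subject", "psqi"), names(ph))
  if (length(miss)) {
    stop("phenotype CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(ph$psqi < 0 | ph$psqi > 21)) {
    stop("psqi scores outside the 0-21 instrument range", call. = FALSE)
  }
  ph$subject <- as.character(ph$subject)
  ph
}

#' Read a region-metadata TSV
#'
#' @param path TSV path with columns `region_id`, `name`, `hemisphere`,
#'   `system`.
#' @return Tibble.
#' @export
read_region_metadata <- function(path) {
  rg <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("region_id", "system"), names(rg))
  if (length(miss)) {
    stop("region metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rg
}

#' Configuration for an end-to-end study run
#'
#' @param connectome_dir Directory of per-subject connectome files.
#' @param phenotype_csv Phenotype CSV path.
#' @param region_tsv Region-metadata TSV path.
#' @param output_dir Directory for all artifacts.
#' @param covariates Covariate columns for partial correlation.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k,repeats k-fold parameters.
#' @param n_perm Permutations per stage.
#' @param top_k Top-region count for stage 2 (default 50).
#' @param seed Integer seed (mandatory).
#' @param fisher_z,absolute_strength,smoothed_p,nested Pipeline flags.
#' @return A `run_config` list.
#' @export
run_config <- function(connectome_dir, phenotype_csv, region_tsv,
                       output_dir, covariates = c("age", "sex", "education"),
                       scheme = c("loocv", "kfold"), k = 10L, repeats = 20L,
                       n_perm = 1000L, top_k = 50L, seed,
                       fisher_z = FALSE, absolute_strength = FALSE,
                       smoothed_p = FALSE, nested = FALSE) {
  scheme <- match.arg(scheme)
  .assert_scalar_count(seed, "seed", min = 0L)
  structure(list(connectome_dir = connectome_dir,
                 phenotype_csv = phenotype_csv, region_tsv = region_tsv,
                 output_dir = output_dir, covariates = covariates,
                 scheme = scheme, k = as.integer(k),
                 repeats = as.integer(repeats),
                 n_perm = as.integer(n_perm), top_k = as.integer(top_k),
                 seed = as.integer(seed), fisher_z = fisher_z,
                 absolute_strength = absolute_strength,
                 smoothed_p = smoothed_p, nested = nested),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path YAML/JSON file with fields matching [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Read a cohort configuration from YAML or JSON
#'
#' @param path YAML/JSON file with fields matching [cohort_config()]; the
#'   seed is mandatory.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cohort_config, vals)
}

#' Run the full two-stage prediction study
#'
#' End-to-end driver: reads connectomes, phenotypes and region metadata;
#' extracts nodal strength features; runs the cross-validated prediction and
#' its permutation test; fits the full-sample contribution model and selects
#' the top regions; re-runs prediction and permutation on the edge-level
#' features among those regions; aggregates edge weights into network-pair
#' sums. Every intermediate table is written under `config$output_dir`
#' together with a single `study_report.json` carrying all metrics,
#' p-values, the configuration echo, its hash and the package version.
#' Re-running with an identical configuration (including seed) reproduces
#' `study_report.json` byte for byte; wall-clock timings go to `study.log`
#' only.
#'
#' @param config A [run_config()].
#' @return The study report (list), invisibly.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "study.log")
  cat("study started\n", file = log_path)
  t0 <- Sys.time()
  stage <- function(msg) {
    cat(sprintf("[%+.1fs] %s\n", as.numeric(Sys.time() - t0, "secs"), msg),
        file = log_path, append = TRUE)
  }

  connectomes <- read_connectomes(config$connectome_dir)
  phenotypes <- read_phenotypes(config$phenotype_csv)
  regions <- read_region_metadata(config$region_tsv)

  only_conn <- setdiff(names(connectomes), phenotypes$subject)
  only_ph <- setdiff(phenotypes$subject, names(connectomes))
  if (length(only_conn) || length(only_ph)) {
    stop("subject ids disagree; connectomes only: [",
         paste(only_conn, collapse = ", "), "]; phenotypes only: [",
         paste(only_ph, collapse = ", "), "]", call. = FALSE)
  }
  R <- nrow(connectomes[[1]])
  if (R != nrow(regions)) {
    stop("region count mismatch: connectomes have ", R,
         " regions, metadata has ", nrow(regions), call. = FALSE)
  }
  stage("inputs read")

  # stage 1: nodal strength features
  nodal <- nodal_strength_features(connectomes,
                                   fisher_z = config$fisher_z,
                                   absolute = config$absolute_strength)
  readr::write_csv(nodal, file.path(out, "nodal_features.csv"))
  stage("nodal features extracted")

  run_cv <- function(feats) {
    if (config$scheme == "loocv") {
      run_loocv(feats, phenotypes, config$covariates)
    } else {
      run_repeated_kfold(feats, phenotypes, config$covariates,
                         k = config$k, repeats = config$repeats,
                         seed = config$seed)
    }
  }
  nodal_cv <- run_cv(nodal)
  readr::write_csv(nodal_cv$predictions, file.path(out, "predictions.csv"))
  stage("nodal CV done")

  nodal_perm <- permutation_test(nodal, phenotypes, config$covariates,
                                 scheme = config$scheme, k = config$k,
                                 repeats = config$repeats,
                                 n_perm = config$n_perm,
                                 seed = config$seed,
                                 smoothed = config$smoothed_p)
  write_null_distribution(nodal_perm,
                          file.path(out, "null_distribution.tsv"))
  stage("nodal permutation done")

  contrib <- full_sample_weights(nodal, phenotypes, k = config$top_k)
  region_tab <- dplyr::left_join(
    dplyr::rename(contrib$weights, region_id = "feature_id"),
    regions, by = "region_id"
  )
  readr::write_csv(region_tab, file.path(out, "region_contributions.csv"))
  stage("full-sample contributions done")

  edge <- edge_level_prediction(connectomes, contrib$top_k_ids, phenotypes,
                                covariates = config$covariates,
                                scheme = config$scheme, k = config$k,
                                repeats = config$repeats,
                                seed = config$seed,
                                nested = config$nested)
  edge_perm <- if (!config$nested) {
    permutation_test(edge$features, phenotypes, config$covariates,
                     scheme = config$scheme, k = config$k,
                     repeats = config$repeats, n_perm = config$n_perm,
                     seed = config$seed, smoothed = config$smoothed_p)
  }
  if (!is.null(edge$edge_weights)) {
    readr::write_csv(edge$edge_weights,
                     file.path(out, "edge_contributions.csv"))
  }
  stage("edge stage done")

  network <- if (!is.null(edge$edge_weights)) {
    network_aggregate(edge$edge_weights, regions)
  }
  if (!is.null(network)) {
    net_df <- tibble::as_tibble(unclass(network), rownames = "system")
    readr::write_tsv(net_df, file.path(out, "network_matrix.tsv"))
  }
  stage("network aggregation done")

  config_plain <- unclass(config)
  report <- list(
    package = "connpredict",
    version = as.character(packageVersion("connpredict")),
    config = config_plain,
    config_hash = rlang::hash(config_plain),
    n_subjects = nrow(phenotypes),
    n_regions = R,
    n_nodal_features = ncol(nodal) - 1L,
    n_edge_features = if (!is.null(edge$features)) {
      ncol(edge$features) - 1L
    } else {
      as.integer(config$top_k * (config$top_k - 1) / 2)
    },
    nodal = c(as.list(nodal_cv$metrics),
              list(p_r = nodal_perm$p_r,
                   p_partial_r = nodal_perm$p_partial_r,
                   p_mae = nodal_perm$p_mae)),
    top_regions = contrib$top_k_ids,
    edge = c(as.list(edge$cv$metrics),
             if (!is.null(edge_perm)) {
               list(p_r = edge_perm$p_r,
                    p_partial_r = edge_perm$p_partial_r,
                    p_mae = edge_perm$p_mae)
             }),
    network_total_abs_weight = if (!is.null(network)) {
      sum(unclass(network)[upper.tri(network, diag = TRUE)])
    }
  )
  jsonlite::write_json(report, file.path(out, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("report written")
  invisible(report)
}
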