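#' Full-sample contribution weights and top-k feature ranking
#'
#' Fits one relevance vector regression on all subjects (features min-max
#' scaled across the full sample, mirroring the training transform used in
#' cross-validation), back-projects the sample weights to per-feature
#' contribution weights, and ranks features by absolute weight. The top
#' `k` features (default 50) are flagged as the most contributing. Exact
#' ties in absolute weight are broken by atlas order, so the ranking is
#' deterministic.
#'
#' @param features Tibble with `subject` column plus feature columns, or a
#'   matrix with subject rownames.
#' @param phenotypes Phenotype tibble with `subject` and `psqi` (or a bare
#'   numeric score vector aligned to the feature rows).
#' @param k Number of top features to select.
#' @param max_iter Maximum RVR update iterations.
#' @return A `contribution_report`: list with `weights` (tibble
#'   `feature_id`, `weight`, `abs_rank`, `in_top_k`), `top_k_ids`, `k` and
#'   the fitted `model`.
#' @export
full_sample_weights <- function(features, phenotypes, k = 50L,
                                max_iter = 1000L) {
  if (is.numeric(phenotypes) && is.null(dim(phenotypes))) {
    X <- if (is.matrix(features)) {
      features
    } else {
      df <- as.data.frame(features)
      as.matrix(df[setdiff(names(df), "subject")])
    }
    y <- as.numeric(phenotypes)
  } else {
    inp <- .align_inputs(features, phenotypes, character())
    X <- inp$X
    y <- inp$y
  }
  .assert_scalar_count(k, "k", min = 1L)
  Xs <- minmax_scale_fold(X)$train
  model <- fit_rvr(Xs, y, max_iter = max_iter)
  w <- back_project_weights(model)
  ord <- order(-abs(w$weight), seq_along(w$weight))
  abs_rank <- integer(nrow(w))
  abs_rank[ord] <- seq_len(nrow(w))
  k_eff <- min(k, nrow(w))
  weights <- tibble::tibble(feature_id = w$feature_id, weight = w$weight,
                            abs_rank = abs_rank,
                            in_top_k = abs_rank <= k_eff)
  structure(list(weights = weights,
                 top_k_ids = weights$feature_id[ord[seq_len(k_eff)]],
                 k = k_eff, model = model),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("<contribution_report> ", nrow(x$weights), " features, top k = ",
      x$k, "\n", sep = "")
  top <- utils::head(x$weights[order(x$weights$abs_rank), ], 5L)
  cat("  leading features: ",
      paste(sprintf("%s (%.3g)", top$feature_id, top$weight),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.contribution_report <- function(x, ...) x$weights

#' Second-stage edge-level prediction among top regions
#'
#' Builds the upper-triangular connectivity features among a previously
#' selected region set (K(K-1)/2 features; 1,225 for K = 50), re-runs the
#' leave-one-out (or repeated k-fold) prediction pipeline on them, and fits
#' a full-sample edge-weight model whose top `k_top_edges` edges are
#' flagged. With `nested = TRUE` the region selection itself is redone
#' inside each training fold (leave-one-out only), avoiding the circularity
#' of re-using full-sample top regions; the default mirrors the two-stage
#' convention in which the stage-2 accuracy is interpretive.
#'
#' @param connectomes Named list of connectivity matrices or a
#'   `synthetic_cohort`.
#' @param top_regions Character vector of region ids (>= 2) from a prior
#'   nodal-stage report. Ignored when `nested = TRUE`.
#' @inheritParams run_loocv
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k,repeats,seed Passed to [run_repeated_kfold()] when
#'   `scheme = "kfold"`.
#' @param k_top_edges Number of top edges to flag (default 50).
#' @param nested Redo top-region selection inside each training fold.
#' @param n_top_regions Region-set size used when `nested = TRUE`.
#' @return List with `cv` (a `cv_result`), `edges` (a `contribution_report`
#'   over edges, `NULL` when nested), `edge_weights` (tibble with
#'   `region_i`, `region_j`, `weight`, `abs_rank`, `in_top_k`) and
#'   `features` (the edge feature table).
#' @export
edge_level_prediction <- function(connectomes, top_regions, phenotypes,
                                  covariates = c("age", "sex", "education"),
                                  scheme = c("loocv", "kfold"),
                                  k = 10L, repeats = 20L, seed = NULL,
                                  k_top_edges = 50L, nested = FALSE,
                                  n_top_regions = 50L, max_iter = 1000L) {
  scheme <- match.arg(scheme)
  if (inherits(connectomes, "synthetic_cohort")) {
    connectomes <- connectomes$connectomes
  }
  if (nested) {
    return(.nested_edge_loocv(connectomes, phenotypes, covariates,
                              n_top_regions, max_iter))
  }
  if (length(top_regions) < 2L) {
    stop("need at least 2 top regions for edge-level features",
         call. = FALSE)
  }
  feats <- edge_feature_table(connectomes, top_regions)
  cv <- if (scheme == "loocv") {
    run_loocv(feats, phenotypes, covariates, max_iter = max_iter)
  } else {
    run_repeated_kfold(feats, phenotypes, covariates, k = k,
                       repeats = repeats, seed = seed, max_iter = max_iter)
  }
  edges <- full_sample_weights(feats, phenotypes, k = k_top_edges,
                               max_iter = max_iter)
  ew <- edges$weights
  parts <- strsplit(ew$feature_id, "--", fixed = TRUE)
  edge_weights <- tibble::tibble(
    region_i = vapply(parts, `[`, "", 1L),
    region_j = vapply(parts, `[`, "", 2L),
    weight = ew$weight, abs_rank = ew$abs_rank, in_top_k = ew$in_top_k
  )
  list(cv = cv, edges = edges, edge_weights = edge_weights,
       features = feats)
}

# Fully nested variant: per left-out subject, rank regions on the training
# subjects only, then build/scaled edge features for that training-specific
# region set.
.nested_edge_loocv <- function(connectomes, phenotypes, covariates,
                               n_top_regions, max_iter) {
  nodal <- nodal_strength_features(connectomes)
  inp <- .align_inputs(nodal, phenotypes, covariates)
  n <- length(inp$y)
  subjects <- phenotypes$subject
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    rep_i <- full_sample_weights(inp$X[train, , drop = FALSE],
                                 inp$y[train], k = n_top_regions,
                                 max_iter = max_iter)
    feats <- edge_feature_table(connectomes[subjects], rep_i$top_k_ids)
    Xe <- as.matrix(feats[setdiff(names(feats), "subject")])
    sc <- minmax_scale_fold(Xe[train, , drop = FALSE],
                            Xe[i, , drop = FALSE])
    fit <- fit_rvr(sc$train, inp$y[train], max_iter = max_iter)
    pred[i] <- predict(fit, sc$test)
  }
  metrics <- prediction_accuracy(inp$y, pred, inp$Z)
  cv <- .new_cv_result(
    tibble::tibble(subject = subjects, fold = seq_len(n), rep = 1L,
                   observed = inp$y, predicted = pred),
    metrics, metrics, covariates, scheme = "loocv-nested",
    seed = NA_integer_
  )
  list(cv = cv, edges = NULL, edge_weights = NULL, features = NULL)
}

#' Aggregate edge contribution weights into network-pair sums
#'
#' Sums the absolute edge contribution weights over unordered pairs of
#' cognitive systems: entry (a, b) is the total |weight| of edges with one
#' endpoint in system a and the other in system b; the diagonal holds
#' within-system sums. Every scored edge contributes to exactly one
#' unordered pair, so the matrix total equals the sum of all |weights|.
#' Signed sums are kept as an attribute for inspection.
#'
#' @param edge_weights Tibble with columns `region_i`, `region_j`, `weight`
#'   (e.g. from [edge_level_prediction()]).
#' @param regions Region metadata tibble with `region_id` and `system`.
#' @return An S-by-S symmetric matrix of class `network_contribution` with
#'   system labels as dimnames and the signed-sum matrix in attribute
#'   `"signed"`.
#' @export
network_aggregate <- function(edge_weights, regions) {
  stopifnot(all(c("region_i", "region_j", "weight") %in%
                  names(edge_weights)),
            all(c("region_id", "system") %in% names(regions)))
  sys_of <- setNames(regions$system, regions$region_id)
  miss <- setdiff(unique(c(edge_weights$region_i, edge_weights$region_j)),
                  names(sys_of))
  if (length(miss)) {
    stop("region(s) without a system label: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  labels <- intersect(.systems, unique(regions$system))
  labels <- c(labels, setdiff(unique(regions$system), .systems))
  S <- length(labels)
  M <- matrix(0, S, S, dimnames = list(labels, labels))
  Msign <- M
  a <- match(sys_of[edge_weights$region_i], labels)
  b <- match(sys_of[edge_weights$region_j], labels)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  for (e in seq_along(lo)) {
    M[lo[e], hi[e]] <- M[lo[e], hi[e]] + abs(edge_weights$weight[e])
    Msign[lo[e], hi[e]] <- Msign[lo[e], hi[e]] + edge_weights$weight[e]
  }
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  Msign[lower.tri(Msign)] <- t(Msign)[lower.tri(Msign)]
  structure(M, signed = Msign, class = c("network_contribution", "matrix"))
}

#' @rdname network_aggregate
#' @param object A `network_contribution` matrix.
#' @param ... Unused.
#' @export
autoplot.network_contribution <- function(object, ...) {
  labels <- rownames(object)
  df <- tidyr::expand_grid(system_a = labels, system_b = labels)
  df$weight <- as.vector(t(unclass(object)))
  df$system_a <- factor(df$system_a, levels = labels)
  df$system_b <- factor(df$system_b, levels = rev(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$system_a, y = .data$system_b,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Sum |weight|",
                  title = "Network-pair contribution weights")
}
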