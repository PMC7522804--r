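#' Permutation significance of prediction accuracy
#'
#' Re-runs the entire cross-validated prediction pipeline `n_perm` times
#' against score vectors shuffled without replacement (one global shuffle per
#' permutation, applied consistently across all folds), building null
#' distributions of the correlation and the MAE. Covariates are never
#' permuted. The p-value of the correlation is the proportion of
#' permutations with a null correlation at least as high as the observed
#' one; the p-value of the MAE is the proportion with a null MAE at least as
#' low as the observed one (ties count as exceeding). Because per-fold
#' feature scaling and kernels do not depend on the scores, they are
#' computed once and re-used across permutations; every permutation still
#' refits the full set of per-fold models.
#'
#' The literal proportion can be exactly zero; `smoothed = TRUE` reports the
#' add-one estimate `(b + 1) / (n_perm + 1)` instead, which never is. Both
#' counts are stored so either definition can be recovered.
#'
#' @inheritParams run_repeated_kfold
#' @param scheme `"loocv"` or `"kfold"`.
#' @param n_perm Number of permutations (1,000 in the canonical analysis).
#' @param seed Integer seed; permutation b uses the sub-seed `(seed, b)`.
#' @param smoothed Report add-one smoothed p-values.
#' @return A `permutation_result` object.
#' @export
permutation_test <- function(features, phenotypes,
                             covariates = c("age", "sex", "education"),
                             scheme = c("loocv", "kfold"),
                             k = 10L, repeats = 20L,
                             n_perm = 1000L, seed, smoothed = FALSE,
                             max_iter = 1000L) {
  scheme <- match.arg(scheme)
  .assert_scalar_count(n_perm, "n_perm", min = 1L)
  .assert_scalar_count(seed, "seed", min = 0L)
  inp <- .align_inputs(features, phenotypes, covariates)
  n <- length(inp$y)

  # fold caches shared by the observed run and every permutation
  if (scheme == "loocv") {
    cache_sets <- list(.make_fold_caches(inp$X, as.list(seq_len(n))))
  } else {
    if (k > n) stop("k (", k, ") exceeds the number of subjects (", n, ")",
                    call. = FALSE)
    cache_sets <- lapply(seq_len(repeats), function(rp) {
      .make_fold_caches(inp$X, .kfold_partition(n, k, .sub_seed(seed, rp)))
    })
  }

  run_once <- function(y) {
    per <- lapply(cache_sets, function(cs) {
      pred <- .cv_predict(cs, y, max_iter = max_iter)$pred
      prediction_accuracy(y, pred, inp$Z)
    })
    m <- dplyr::bind_rows(per)
    tibble::tibble(r = mean(m$r), partial_r = mean(m$partial_r),
                   mae = mean(m$mae))
  }

  observed <- run_once(inp$y)

  null_rows <- vector("list", n_perm)
  failed <- integer()
  for (b in seq_len(n_perm)) {
    set.seed(.sub_seed(seed, 100000L + b))
    y_perm <- inp$y[sample.int(n)]
    res <- tryCatch(run_once(y_perm), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, b)
    } else {
      null_rows[[b]] <- dplyr::bind_cols(tibble::tibble(perm = b), res)
    }
  }
  if (length(failed) > 0.01 * n_perm) {
    stop(length(failed), " of ", n_perm, " permutation runs failed ",
         "(more than 1%); aborting", call. = FALSE)
  }
  null <- dplyr::bind_rows(null_rows)
  n_eff <- nrow(null)
  if (n_eff == 0L) stop("all permutation runs failed", call. = FALSE)

  counts <- c(r = sum(null$r >= observed$r),
              partial_r = sum(null$partial_r >= observed$partial_r),
              mae = sum(null$mae <= observed$mae))
  p_literal <- counts / n_eff
  p_smooth <- (counts + 1) / (n_eff + 1)
  p <- if (smoothed) p_smooth else p_literal

  structure(
    list(observed = observed, null = null,
         p_r = unname(p["r"]), p_partial_r = unname(p["partial_r"]),
         p_mae = unname(p["mae"]),
         counts = counts, n_perm = n_perm, n_effective = n_eff,
         failed = failed, smoothed = smoothed,
         scheme = if (scheme == "kfold") {
           list(name = "kfold", k = k, repeats = repeats)
         } else {
           "loocv"
         },
         seed = as.integer(seed)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$n_effective, " of ", x$n_perm,
      " permutations\n", sep = "")
  cat("  observed r = ", format(x$observed$r, digits = 3),
      " (p = ", format(x$p_r, digits = 3), "), MAE = ",
      format(x$observed$mae, digits = 3),
      " (p = ", format(x$p_mae, digits = 3), ")",
      if (x$smoothed) " [smoothed]", "\n", sep = "")
  invisible(x)
}

#' Tidiers for permutation results
#'
#' `tidy()` returns the null distribution (one row per permutation);
#' `glance()` the observed metrics and p-values.
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @export
tidy.permutation_result <- function(x, ...) x$null

#' @rdname tidy.permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    observed_r = x$observed$r,
    observed_partial_r = x$observed$partial_r,
    observed_mae = x$observed$mae,
    p_r = x$p_r, p_partial_r = x$p_partial_r, p_mae = x$p_mae,
    n_perm = x$n_perm, n_effective = x$n_effective,
    n_failed = length(x$failed), smoothed = x$smoothed
  )
}

#' @rdname tidy.permutation_result
#' @param object A `permutation_result`.
#' @export
autoplot.permutation_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$null[, c("r", "mae")],
                              cols = c("r", "mae"),
                              names_to = "metric", values_to = "value")
  obs <- tibble::tibble(metric = c("r", "mae"),
                        value = c(object$observed$r, object$observed$mae))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$value),
                        colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "Null metric value", y = "Permutations",
                  title = "Permutation null distributions (red = observed)")
}

#' Write a permutation null distribution to TSV
#'
#' @param x A `permutation_result`.
#' @param path Output TSV path.
#' @export
write_null_distribution <- function(x, path) {
  stopifnot(inherits(x, "permutation_result"))
  readr::write_tsv(x$null, path)
  invisible(path)
}
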