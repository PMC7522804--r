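# Leakage-safe cross-validated prediction.
#
# The fold machinery is shared by LOOCV, repeated k-fold and the permutation
# test: per fold the scaled training kernel and the train-to-test kernel
# depend only on the features, so they are computed once (".fold caches") and
# re-used for every response vector fitted against them. This is what makes
# 1,000-permutation runs affordable: permuting the scores never changes the
# feature side of the pipeline.

# Build covariate design matrix from phenotype columns. Sex is normalised to
# 0/1; other categorical covariates are one-hot encoded with the first level
# dropped.
.covariate_matrix <- function(phenotypes, covariates) {
  if (length(covariates) == 0L) return(NULL)
  missing <- setdiff(covariates, names(phenotypes))
  if (length(missing)) {
    stop("phenotype table lacks covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(covariates, function(v) {
    x <- phenotypes[[v]]
    if (v == "sex" || (!is.numeric(x) && length(unique(x)) <= 2L)) {
      x <- .normalize_sex(x, v)
      m <- matrix(x, ncol = 1L, dimnames = list(NULL, v))
    } else if (is.numeric(x)) {
      m <- matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, v))
    } else {
      f <- factor(x)
      m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(m) <- paste0(v, levels(f)[-1L])
    }
    m
  })
  Z <- do.call(cbind, cols)
  if (anyNA(Z)) {
    stop("missing values in covariate column(s)", call. = FALSE)
  }
  Z
}

.normalize_sex <- function(x, name = "sex") {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("numeric `", name, "` must be coded 0/1", call. = FALSE)
    }
    return(as.numeric(x))
  }
  x <- toupper(as.character(x))
  map <- c("M" = 0, "F" = 1, "0" = 0, "1" = 1)
  if (!all(x %in% names(map))) {
    stop("`", name, "` values must be in {M, F, 0, 1}", call. = FALSE)
  }
  unname(map[x])
}

#' Prediction accuracy metrics
#'
#' Pearson correlation, covariate-controlled partial correlation, and mean
#' absolute error between observed and predicted scores. The partial
#' correlation is the Pearson correlation of the two residual vectors after
#' regressing observed and predicted scores each on an intercept plus the
#' covariates; the MAE is always computed on the raw (unresidualised)
#' scores.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param covariates Optional numeric covariate matrix (subjects in rows).
#' @return Tibble with columns `r`, `partial_r`, `mae`.
#' @export
prediction_accuracy <- function(observed, predicted, covariates = NULL) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n - 2L - q < 1L) {
    stop("too few subjects (", n, ") for ", q,
         " covariate(s): no residual degrees of freedom", call. = FALSE)
  }
  r <- cor(observed, predicted)
  partial_r <- if (q == 0L) {
    r
  } else {
    Z <- cbind(1, as.matrix(covariates))
    res_o <- stats::lm.fit(Z, observed)$residuals
    res_p <- stats::lm.fit(Z, predicted)$residuals
    cor(res_o, res_p)
  }
  tibble::tibble(r = r, partial_r = partial_r,
                 mae = mean(abs(observed - predicted)))
}

# ---- fold machinery ---------------------------------------------------------

# folds: list of integer vectors of test indices (a partition of 1..n).
# poison: replace held-out rows with NaN in the matrix handed to the
# scaling/training path (a leakage spy: any use of test rows upstream of
# prediction would contaminate the fit). The true test rows are still used,
# scaled with the train-derived parameters, for prediction.
.make_fold_caches <- function(X, folds, poison = FALSE) {
  n <- nrow(X)
  lapply(folds, function(test) {
    train <- setdiff(seq_len(n), test)
    Xw <- X
    if (poison) Xw[test, ] <- NaN
    sc <- minmax_scale_fold(Xw[train, , drop = FALSE],
                            X[test, , drop = FALSE])
    n_tr <- length(train)
    list(train = train, test = test, n_tr = n_tr,
         Phi = cbind(tcrossprod(sc$train), 1),
         Ktest = tcrossprod(sc$test, sc$train))
  })
}

# Fit the RVR core against cached fold kernels for one response vector and
# return out-of-sample predictions (plus fitted cores when keep_fits).
.cv_predict <- function(caches, y, max_iter = 1000L, keep_fits = FALSE) {
  n <- length(y)
  pred <- rep(NA_real_, n)
  fits <- if (keep_fits) vector("list", length(caches))
  for (f in seq_along(caches)) {
    cc <- caches[[f]]
    y_tr <- y[cc$train]
    fit <- tryCatch({
      if (var(y_tr) == 0) {
        list(active = integer(), mu = numeric(), bias_only = y_tr[1])
      } else {
        .rvr_fit_core(cc$Phi, y_tr, 1 / cc$n_tr,
                      max(0.1 * var(y_tr), 1e-8),
                      bias_index = cc$n_tr, prune_thresh = 1e9,
                      tol = 1e-6, max_iter = as.integer(max_iter),
                      sigma2_floor = 1e-12, fixed_alpha = FALSE,
                      fixed_sigma2 = FALSE)
      }
    }, error = function(e) {
      stop("fold ", f, ": ", conditionMessage(e), call. = FALSE)
    })
    if (!is.null(fit$bias_only)) {
      pred[cc$test] <- fit$bias_only
    } else {
      active <- as.integer(fit$active)
      mu <- as.numeric(fit$mu)
      is_bias <- active == cc$n_tr
      kern <- active[!is_bias] + 1L
      p_f <- if (length(kern)) {
        as.vector(cc$Ktest[, kern, drop = FALSE] %*% mu[!is_bias])
      } else {
        rep(0, length(cc$test))
      }
      pred[cc$test] <- p_f + if (any(is_bias)) mu[is_bias] else 0
    }
    if (keep_fits) fits[[f]] <- fit
  }
  if (keep_fits) list(pred = pred, fits = fits) else list(pred = pred)
}

.kfold_partition <- function(n, k, seed) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  set.seed(seed)
  idx <- sample.int(n)
  split(idx, rep(seq_len(k), times = sizes))
}

.align_inputs <- function(features, phenotypes, covariates) {
  stopifnot(is.data.frame(phenotypes), "subject" %in% names(phenotypes),
            "psqi" %in% names(phenotypes))
  if (anyDuplicated(phenotypes$subject)) {
    stop("duplicate subject ids in phenotype table", call. = FALSE)
  }
  X <- .feature_matrix(features, phenotypes$subject)
  y <- as.numeric(phenotypes$psqi)
  if (anyNA(y)) stop("missing scores in phenotype table", call. = FALSE)
  Z <- .covariate_matrix(phenotypes, covariates)
  list(X = X, y = y, Z = Z)
}

.new_cv_result <- function(predictions, metrics, metrics_by_repeat,
                           covariates, scheme, seed) {
  structure(list(predictions = predictions, metrics = metrics,
                 metrics_by_repeat = metrics_by_repeat,
                 covariates_used = covariates, scheme = scheme, seed = seed),
            class = "cv_result")
}

# ---- user-facing CV runners -------------------------------------------------

#' Leave-one-out cross-validated prediction
#'
#' For each subject in turn: min-max scale every feature on the remaining
#' n - 1 subjects, apply those scaling parameters to the held-out subject,
#' fit the relevance vector regression on the training subjects, and predict
#' the held-out score. Accuracy is summarised as the Pearson correlation,
#' the covariate-controlled partial correlation, and the MAE between
#' observed and predicted scores.
#'
#' @param features Tibble with a `subject` column plus numeric feature
#'   columns (or a matrix with subject rownames).
#' @param phenotypes Tibble with `subject`, `psqi` and any covariate
#'   columns.
#' @param covariates Character vector of phenotype columns to control for in
#'   the partial correlation (default age, sex, education).
#' @param max_iter Maximum RVR update iterations per fold.
#' @return A `cv_result` object; see [tidy.cv_result()] /
#'   [glance.cv_result()].
#' @export
run_loocv <- function(features, phenotypes,
                      covariates = c("age", "sex", "education"),
                      max_iter = 1000L) {
  inp <- .align_inputs(features, phenotypes, covariates)
  n <- length(inp$y)
  if (n < 5L) stop("need at least 5 subjects", call. = FALSE)
  folds <- as.list(seq_len(n))
  caches <- .make_fold_caches(inp$X, folds)
  pred <- .cv_predict(caches, inp$y, max_iter = max_iter)$pred
  metrics <- prediction_accuracy(inp$y, pred, inp$Z)
  predictions <- tibble::tibble(subject = phenotypes$subject,
                                fold = seq_len(n), rep = 1L,
                                observed = inp$y, predicted = pred)
  .new_cv_result(predictions, metrics, metrics,
                 covariates, scheme = "loocv", seed = NA_integer_)
}

#' Repeated k-fold cross-validated prediction
#'
#' Random partition into k near-equal folds (the first `n %% k` folds take
#' the extra subject), repeated `repeats` times with partitions seeded by
#' `(seed, repeat)`. Metrics are computed per repeat and reported as the
#' mean over repeats.
#'
#' @inheritParams run_loocv
#' @param k Number of folds.
#' @param repeats Number of random re-partitions.
#' @param seed Integer seed for the partitions.
#' @return A `cv_result` object with per-repeat metrics in
#'   `metrics_by_repeat`.
#' @export
run_repeated_kfold <- function(features, phenotypes,
                               covariates = c("age", "sex", "education"),
                               k = 10L, repeats = 20L, seed,
                               max_iter = 1000L) {
  inp <- .align_inputs(features, phenotypes, covariates)
  n <- length(inp$y)
  .assert_scalar_count(k, "k", min = 2L)
  .assert_scalar_count(repeats, "repeats", min = 1L)
  .assert_scalar_count(seed, "seed", min = 0L)
  if (k > n) stop("k (", k, ") exceeds the number of subjects (", n, ")",
                  call. = FALSE)
  preds <- vector("list", repeats)
  per_rep <- vector("list", repeats)
  for (rp in seq_len(repeats)) {
    folds <- .kfold_partition(n, k, .sub_seed(seed, rp))
    caches <- .make_fold_caches(inp$X, folds)
    pred <- .cv_predict(caches, inp$y, max_iter = max_iter)$pred
    fold_of <- integer(n)
    for (f in seq_along(folds)) fold_of[folds[[f]]] <- f
    preds[[rp]] <- tibble::tibble(subject = phenotypes$subject,
                                  fold = fold_of, rep = rp,
                                  observed = inp$y, predicted = pred)
    per_rep[[rp]] <- prediction_accuracy(inp$y, pred, inp$Z)
  }
  metrics_by_repeat <- dplyr::bind_rows(per_rep, .id = NULL)
  metrics_by_repeat$rep <- seq_len(repeats)
  metrics <- tibble::tibble(r = mean(metrics_by_repeat$r),
                            partial_r = mean(metrics_by_repeat$partial_r),
                            mae = mean(metrics_by_repeat$mae))
  .new_cv_result(dplyr::bind_rows(preds), metrics, metrics_by_repeat,
                 covariates, scheme = list(name = "kfold", k = k,
                                           repeats = repeats),
                 seed = as.integer(seed))
}

#' @export
print.cv_result <- function(x, ...) {
  sch <- if (is.list(x$scheme)) {
    paste0(x$scheme$name, " (k = ", x$scheme$k, ", repeats = ",
           x$scheme$repeats, ")")
  } else {
    x$scheme
  }
  cat("<cv_result> scheme: ", sch, "\n", sep = "")
  cat("  r = ", format(x$metrics$r, digits = 3),
      ", partial r = ", format(x$metrics$partial_r, digits = 3),
      " (controlling ", paste(x$covariates_used, collapse = ", "),
      "), MAE = ", format(x$metrics$mae, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidiers for cross-validation results
#'
#' `tidy()` returns the per-subject out-of-sample predictions; `glance()`
#' returns the one-row accuracy summary.
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(
      n = length(unique(x$predictions$subject)),
      scheme = if (is.list(x$scheme)) x$scheme$name else x$scheme
    )
  )
}

#' @rdname tidy.cv_result
#' @param object A `cv_result`.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$predictions
  if (max(df$rep) > 1L) {
    df <- dplyr::summarise(dplyr::group_by(df, .data$subject,
                                           .data$observed),
                           predicted = mean(.data$predicted), .groups = "drop")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Observed score", y = "Predicted score",
      title = sprintf("Out-of-sample prediction (r = %.2f, MAE = %.2f)",
                      object$metrics$r, object$metrics$mae)
    )
}
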