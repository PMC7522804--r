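#' Fit a relevance vector regression model
#'
#' Sparse Bayesian regression with a linear dot-product kernel over training
#' samples. The model is \eqn{f(x) = \sum_s \beta_s (x \cdot x_s) + \beta_0}
#' with an explicit zero-mean Gaussian prior \eqn{\beta_i \sim N(0,
#' \alpha_i^{-1})} on every sample weight and on the bias. Hyperparameters
#' \eqn{\alpha} and the noise variance \eqn{\sigma^2} are optimised by
#' type-II maximum likelihood (evidence maximisation) with the classic
#' fixed-point updates; samples whose \eqn{\alpha} diverges are pruned,
#' leaving the relevance vectors. There is no user-tuned regularisation
#' constant.
#'
#' Initialisation is deterministic (all \eqn{\alpha = 1/n}, \eqn{\sigma^2 =
#' 0.1\,\mathrm{var}(y)}), so repeated fits are bit-identical. The log
#' marginal likelihood is recorded at every iteration (`$evidence`).
#'
#' @param x Numeric samples-by-features matrix (or data frame).
#' @param y Numeric response vector.
#' @param prune_threshold Samples with \eqn{\alpha} above this are pruned
#'   (the bias never is).
#' @param tol Convergence threshold on \eqn{\max_i |\Delta \log \alpha_i|}.
#' @param max_iter Maximum update iterations.
#' @param fixed_alpha Optional scalar: clamp all \eqn{\alpha} to this shared
#'   value and skip \eqn{\alpha} updates (the ridge limit; used for
#'   diagnostics and cross-checks).
#' @param fixed_sigma2 Optional scalar: freeze the noise variance.
#' @return An object of class `rvr`.
#' @seealso [back_project_weights()], [predict.rvr()]
#' @export
fit_rvr <- function(x, y, prune_threshold = 1e9, tol = 1e-6,
                    max_iter = 1000L, fixed_alpha = NULL,
                    fixed_sigma2 = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 training samples", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in x or y", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))

  if (var(y) == 0) {
    return(.new_rvr(relevance_indices = integer(),
                    sample_weights = numeric(), bias = y[1],
                    alphas = rep(Inf, n + 1L), noise_variance = 1e-12,
                    gamma = numeric(0), X_train = X, y_train = y,
                    evidence = numeric(0), n_iterations_run = 0L,
                    converged = TRUE, n_jitter = 0L,
                    prune_threshold = prune_threshold, tol = tol))
  }

  Phi <- cbind(tcrossprod(X), 1)
  alpha_init <- if (is.null(fixed_alpha)) 1 / n else fixed_alpha
  sigma2_init <- if (is.null(fixed_sigma2)) 0.1 * var(y) else fixed_sigma2
  core <- .rvr_fit_core(Phi, y, alpha_init, sigma2_init,
                        bias_index = n,  # 0-based last column
                        prune_thresh = prune_threshold, tol = tol,
                        max_iter = as.integer(max_iter),
                        sigma2_floor = 1e-12,
                        fixed_alpha = !is.null(fixed_alpha),
                        fixed_sigma2 = !is.null(fixed_sigma2))
  active <- as.integer(core$active)  # 0-based columns of Phi
  mu <- as.numeric(core$mu)
  is_bias <- active == n
  rel <- active[!is_bias] + 1L
  alphas <- as.numeric(core$alpha)
  alphas[setdiff(seq_len(n + 1L), c(rel, if (any(is_bias)) n + 1L))] <- Inf
  if (length(rel) == 0L) {
    warning("all samples pruned; returning a bias-only model",
            call. = FALSE)
  }
  .new_rvr(relevance_indices = rel,
           sample_weights = setNames(mu[!is_bias], rownames(X)[rel]),
           bias = if (any(is_bias)) mu[is_bias] else 0,
           alphas = alphas,
           noise_variance = core$sigma2,
           gamma = as.numeric(core$gamma),
           X_train = X, y_train = y,
           evidence = as.numeric(core$evidence),
           n_iterations_run = core$n_iter,
           converged = core$converged,
           n_jitter = core$n_jitter,
           prune_threshold = prune_threshold, tol = tol)
}

.new_rvr <- function(...) {
  obj <- list(...)
  obj$kernel <- "linear"
  obj$log_evidence <- if (length(obj$evidence)) {
    obj$evidence[length(obj$evidence)]
  } else {
    NA_real_
  }
  structure(obj, class = "rvr")
}

#' Predict from a fitted RVR model
#'
#' Evaluates \eqn{f(x) = \sum_s \beta_s (x \cdot x_s) + \beta_0} over the
#' retained relevance vectors.
#'
#' @param object Fitted `rvr` model.
#' @param newdata Numeric matrix (or data frame) with the training feature
#'   dimension.
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.rvr <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  p <- ncol(object$X_train)
  if (ncol(X) != p) {
    stop("feature dimension mismatch: model has ", p, ", newdata has ",
         ncol(X), call. = FALSE)
  }
  if (length(object$relevance_indices) == 0L) {
    return(rep(object$bias, nrow(X)))
  }
  Xrel <- object$X_train[object$relevance_indices, , drop = FALSE]
  as.vector(X %*% crossprod(Xrel, object$sample_weights)) + object$bias
}

#' Back-project sample weights to per-feature contribution weights
#'
#' For the linear kernel the model is equivalent to a linear predictor
#' \eqn{w \cdot x + \beta_0} with \eqn{w = \sum_s \beta_s x_s} summed over
#' relevance vectors. The absolute value of each entry of `w` is the
#' feature's contribution to the prediction and is what region/edge rankings
#' are built from.
#'
#' @param model Fitted `rvr` model.
#' @return Tibble with columns `feature_id` and `weight`.
#' @export
back_project_weights <- function(model) {
  stopifnot(inherits(model, "rvr"))
  p <- ncol(model$X_train)
  w <- if (length(model$relevance_indices)) {
    Xrel <- model$X_train[model$relevance_indices, , drop = FALSE]
    as.vector(crossprod(Xrel, model$sample_weights))
  } else {
    rep(0, p)
  }
  tibble::tibble(feature_id = colnames(model$X_train), weight = w)
}

#' @export
print.rvr <- function(x, ...) {
  cat("<rvr> linear-kernel relevance vector regression\n")
  cat("  training samples: ", length(x$y_train),
      "; relevance vectors: ", length(x$relevance_indices), "\n", sep = "")
  cat("  noise variance: ", format(x$noise_variance, digits = 4),
      "; log evidence: ", format(x$log_evidence, digits = 6),
      "; iterations: ", x$n_iterations_run,
      if (isTRUE(x$converged)) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' @rdname back_project_weights
#' @param x Fitted `rvr` model.
#' @param ... Unused.
#' @export
tidy.rvr <- function(x, ...) {
  w <- back_project_weights(x)
  tibble::tibble(term = w$feature_id, estimate = w$weight)
}

#' @export
glance.rvr <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$y_train),
    n_relevance = length(x$relevance_indices),
    noise_variance = x$noise_variance,
    log_evidence = x$log_evidence,
    n_iterations = x$n_iterations_run,
    converged = isTRUE(x$converged)
  )
}

#' Serialize an RVR model to JSON
#'
#' Writes relevance indices, sample weights, hyperparameters, the evidence
#' trace and the stored training features, so the model can be re-read and
#' used for prediction.
#'
#' @param model Fitted `rvr` model.
#' @param path Output file path.
#' @export
write_rvr_json <- function(model, path) {
  stopifnot(inherits(model, "rvr"))
  alphas <- model$alphas
  alphas[!is.finite(alphas)] <- -1  # JSON has no Inf; -1 marks pruned
  obj <- list(
    kernel = model$kernel,
    relevance_indices = model$relevance_indices,
    sample_weights = unname(model$sample_weights),
    bias = model$bias,
    alphas = alphas,
    noise_variance = model$noise_variance,
    evidence_trace = model$evidence,
    n_iterations_run = model$n_iterations_run,
    converged = model$converged,
    config = list(prune_threshold = model$prune_threshold, tol = model$tol),
    feature_ids = colnames(model$X_train),
    X_train = model$X_train,
    y_train = model$y_train
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rvr_json
#' @param path Path to a JSON file written by [write_rvr_json()].
#' @export
read_rvr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  alphas <- obj$alphas
  alphas[alphas < 0] <- Inf
  X <- as.matrix(obj$X_train)
  colnames(X) <- obj$feature_ids
  .new_rvr(relevance_indices = as.integer(obj$relevance_indices),
           sample_weights = as.numeric(obj$sample_weights),
           bias = obj$bias, alphas = alphas,
           noise_variance = obj$noise_variance, gamma = numeric(0),
           X_train = X, y_train = as.numeric(obj$y_train),
           evidence = as.numeric(obj$evidence_trace),
           n_iterations_run = obj$n_iterations_run,
           converged = obj$converged, n_jitter = 0L,
           prune_threshold = obj$config$prune_threshold,
           tol = obj$config$tol)
}
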