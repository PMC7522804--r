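#' Per-fold min-max feature scaling
#'
#' Linearly scales each feature between zero and one across the training
#' rows and applies the same parameters (train minimum and range) to the
#' test rows. Test values may therefore fall outside \[0, 1\]; they are not
#' clipped. A feature with zero training range carries no information and is
#' mapped to 0 in both sets; such features are reported in
#' `constant_features`.
#'
#' @param train Numeric samples-by-features matrix.
#' @param test Optional numeric matrix with the same feature dimension.
#' @return List with `train`, `test` (or `NULL`), `min`, `range` and
#'   `constant_features` (integer column indices).
#' @export
minmax_scale_fold <- function(train, test = NULL) {
  train <- as.matrix(train)
  storage.mode(train) <- "double"
  if (!is.null(test)) {
    test <- as.matrix(test)
    storage.mode(test) <- "double"
    if (ncol(test) != ncol(train)) {
      stop("train and test feature dimensions differ", call. = FALSE)
    }
  }
  mins <- apply(train, 2L, min)
  maxs <- apply(train, 2L, max)
  rng <- maxs - mins
  const <- which(rng == 0)
  rng_safe <- ifelse(rng == 0, 1, rng)
  sc_train <- sweep(sweep(train, 2L, mins, "-"), 2L, rng_safe, "/")
  sc_test <- if (!is.null(test)) {
    sweep(sweep(test, 2L, mins, "-"), 2L, rng_safe, "/")
  }
  if (length(const)) {
    sc_train[, const] <- 0
    if (!is.null(sc_test)) sc_test[, const] <- 0
  }
  list(train = sc_train, test = sc_test, min = mins, range = rng,
       constant_features = const)
}
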