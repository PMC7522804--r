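#' Partial correlation with arbitrary covariate control
#'
#' Residualises `x` and `y` on an intercept plus the covariates by least
#' squares and correlates the residuals. The two-sided p-value comes from
#' the t-transform \eqn{t = r \sqrt{(n - 2 - q) / (1 - r^2)}} with
#' \eqn{n - 2 - q} degrees of freedom (q = number of covariate columns).
#' With no covariates this reduces exactly to the plain Pearson correlation
#' and its textbook test.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix / data frame of covariates.
#' @return One-row tibble with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  Z <- if (is.null(covariates)) {
    matrix(1, n, 1L)
  } else {
    cbind(`(intercept)` = 1, as.matrix(covariates))
  }
  q <- ncol(Z) - 1L
  if (n < q + 3L) {
    stop("need at least q + 3 = ", q + 3L, " observations, got ", n,
         call. = FALSE)
  }
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    bad <- colnames(Z)[qrz$pivot[seq.int(qrz$rank + 1L, ncol(Z))]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res_x <- qr.resid(qrz, x)
  res_y <- qr.resid(qrz, y)
  # a residual that is numerically zero relative to the variable's own scale
  # means the variable lies in the covariate span
  degenerate <- function(res, orig) {
    s <- sd(orig)
    sd(res) <= 1e-10 * if (s > 0) s else 1
  }
  if (degenerate(res_x, x) || degenerate(res_y, y)) {
    stop("degenerate partial correlation: a variable is an exact linear ",
         "combination of the covariates", call. = FALSE)
  }
  r <- cor(res_x, res_y)
  df <- n - 2L - q
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- max(2 * pt(-abs(tstat), df), .Machine$double.xmin)
  tibble::tibble(r = r, p = p, n = n, df = df)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment over a family of p-values, returning adjusted
#' p-values and the rejection mask at level `q`. Input order is preserved
#' and the rejection set is invariant to it.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Tibble with columns `p`, `p_adj`, `significant`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0L) {
    return(tibble::tibble(p = numeric(), p_adj = numeric(),
                          significant = logical()))
  }
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  p_adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = p_adj, significant = p_adj <= q)
}

#' Region-wise screen of nodal strength against a phenotype
#'
#' For each supplied region, computes the partial correlation between that
#' region's nodal strength and a target phenotype column (age, daytime
#' sleepiness, or head motion), controlling for a set of other phenotype
#' columns, then applies Benjamini-Hochberg correction across the regions
#' screened.
#'
#' @param strengths Tibble with `subject` plus one column per region (e.g.
#'   from [nodal_strength_features()]), or a matrix with subject rownames.
#' @param phenotypes Phenotype tibble.
#' @param target Phenotype column to correlate against (e.g. `"age"`,
#'   `"ess"`, `"motion"`).
#' @param controls Phenotype columns to control for.
#' @param regions Optional character vector restricting the screen to a
#'   region subset (typically the top 50 contributing regions).
#' @param q FDR level.
#' @return Tibble with one row per region: `region_id`, `r`, `p`, `p_adj`,
#'   `significant`.
#' @export
strength_covariate_screen <- function(strengths, phenotypes, target,
                                      controls = character(),
                                      regions = NULL, q = 0.05) {
  stopifnot(is.character(target), length(target) == 1L)
  if (!target %in% names(phenotypes)) {
    stop("phenotype table lacks target column `", target, "`",
         call. = FALSE)
  }
  X <- .feature_matrix(strengths, phenotypes$subject)
  if (!is.null(regions)) {
    miss <- setdiff(regions, colnames(X))
    if (length(miss)) {
      stop("unknown region(s) in screen: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, regions, drop = FALSE]
  }
  Z <- .covariate_matrix(phenotypes, controls)
  tvec <- as.numeric(phenotypes[[target]])
  per_region <- purrr::map_dfr(colnames(X), function(rid) {
    pc <- partial_correlation(X[, rid], tvec, Z)
    tibble::tibble(region_id = rid, r = pc$r, p = pc$p)
  })
  adj <- fdr_bh(per_region$p, q = q)
  per_region$p_adj <- adj$p_adj
  per_region$significant <- adj$significant
  per_region
}
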