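#' Pearson connectivity matrix from regional time series
#'
#' Computes the region-by-region Pearson correlation of a time-by-region
#' matrix of regional mean time series. The result is exactly symmetric with
#' a unit diagonal.
#'
#' @param ts Numeric time-by-region matrix (>= 3 time points, no missing
#'   values). Column names, when present, are used as region ids.
#' @param region_ids Optional character vector of region ids overriding the
#'   column names.
#' @return A region-by-region correlation matrix with region ids as
#'   dimnames.
#' @export
compute_connectivity <- function(ts, region_ids = colnames(ts)) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  if (is.null(region_ids)) region_ids <- sprintf("R%03d", seq_len(ncol(ts)))
  stopifnot(length(region_ids) == ncol(ts))
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0)) {
    stop("zero-variance regional signal in region(s): ",
         paste(region_ids[sds == 0], collapse = ", "), call. = FALSE)
  }
  C <- cor(ts)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(region_ids, region_ids)
  C
}

# Shared validation for connectivity matrices.
.check_connectivity <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) {
    stop("connectivity matrix must be square", call. = FALSE)
  }
  if (max(abs(C - t(C))) > 1e-12) {
    stop("connectivity matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(C) - 1) > 1e-12)) {
    stop("connectivity matrix diagonal must be exactly 1", call. = FALSE)
  }
  if (max(abs(C)) > 1 + 1e-12) {
    stop("connectivity values must lie in [-1, 1]", call. = FALSE)
  }
  invisible(C)
}

#' Nodal connectivity strength
#'
#' The degree-like centrality used as the per-region feature: the signed sum
#' of a region's connectivity to all other regions (for an R-region atlas,
#' R - 1 terms per region). No absolute value and no Fisher z transform are
#' applied by default; both are available as options because conventions
#' differ across studies.
#'
#' @param C Connectivity matrix (symmetric, unit diagonal).
#' @param fisher_z Apply `atanh` to each off-diagonal correlation before
#'   summing.
#' @param absolute Sum absolute correlations.
#' @return Named numeric vector of per-region strengths.
#' @export
nodal_strength <- function(C, fisher_z = FALSE, absolute = FALSE) {
  .check_connectivity(C)
  V <- C
  diag(V) <- 0
  if (fisher_z) V <- atanh(pmin(pmax(V, -1 + 1e-15), 1 - 1e-15))
  if (absolute) V <- abs(V)
  rowSums(V)
}

#' Nodal strength feature table for a set of subjects
#'
#' @param connectomes Named list of connectivity matrices (names = subject
#'   ids), or a `synthetic_cohort`.
#' @inheritParams nodal_strength
#' @return Tibble with a `subject` column and one numeric column per region.
#' @export
nodal_strength_features <- function(connectomes, fisher_z = FALSE,
                                    absolute = FALSE) {
  if (inherits(connectomes, "synthetic_cohort")) {
    connectomes <- connectomes$connectomes
  }
  stopifnot(is.list(connectomes), length(connectomes) >= 1L,
            !is.null(names(connectomes)))
  S <- t(vapply(connectomes, nodal_strength, fisher_z = fisher_z,
                absolute = absolute,
                FUN.VALUE = numeric(nrow(connectomes[[1]]))))
  dplyr::bind_cols(tibble::tibble(subject = names(connectomes)),
                   tibble::as_tibble(S))
}

#' Edge-level connectivity features among a region subset
#'
#' Extracts the strictly upper-triangular connectivity values among a subset
#' of K regions, in lexicographic atlas order, yielding K(K-1)/2 features
#' (1,225 for the canonical K = 50).
#'
#' @param C Connectivity matrix with region ids as dimnames.
#' @param subset Character vector of region ids (>= 2, no duplicates).
#' @return Tibble with columns `region_i`, `region_j`, `value` in index-map
#'   order.
#' @export
extract_edge_features <- function(C, subset) {
  .check_connectivity(C)
  ids <- rownames(C)
  if (is.null(ids)) stop("connectivity matrix must carry region ids",
                         call. = FALSE)
  if (anyDuplicated(subset)) {
    stop("duplicate region ids in `subset`", call. = FALSE)
  }
  if (length(subset) < 2L) stop("`subset` needs at least 2 regions",
                                call. = FALSE)
  missing <- setdiff(subset, ids)
  if (length(missing)) {
    stop("unknown region id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # keep atlas order, not the order regions were listed in
  subset <- ids[sort(match(subset, ids))]
  map <- .edge_index_map(subset)
  pos <- cbind(match(map$region_i, ids), match(map$region_j, ids))
  tibble::tibble(region_i = map$region_i, region_j = map$region_j,
                 value = C[pos])
}

#' Subjects-by-edges feature table
#'
#' @param connectomes Named list of connectivity matrices or a
#'   `synthetic_cohort`.
#' @param subset Region ids defining the edge set.
#' @return Tibble with `subject` plus one column per edge, named
#'   `"<region_i>--<region_j>"` in index-map order.
#' @export
edge_feature_table <- function(connectomes, subset) {
  if (inherits(connectomes, "synthetic_cohort")) {
    connectomes <- connectomes$connectomes
  }
  stopifnot(is.list(connectomes), !is.null(names(connectomes)))
  rows <- lapply(connectomes, extract_edge_features, subset = subset)
  first <- rows[[1]]
  vals <- do.call(rbind, lapply(rows, function(r) r$value))
  colnames(vals) <- paste0(first$region_i, "--", first$region_j)
  dplyr::bind_cols(tibble::tibble(subject = names(connectomes)),
                   tibble::as_tibble(vals))
}
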