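# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a user seed and a stream index.
# Keeps every derived seed strictly below 2^31 - 1.
.sub_seed <- function(seed, idx) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer(((abs(seed) %% 100003) * 10007 + idx) %% 2147483647)
}

# Strictly upper-triangular (i < j) index map in lexicographic atlas order.
# `ids` is the ordered vector of region identifiers; returns a tibble with the
# integer positions and the ids of each unordered pair.
.edge_index_map <- function(ids) {
  K <- length(ids)
  stopifnot(K >= 2L)
  pos_i <- rep.int(seq_len(K - 1L), times = (K - 1L):1L)
  pos_j <- unlist(lapply(seq_len(K - 1L), function(a) seq.int(a + 1L, K)),
                  use.names = FALSE)
  tibble::tibble(
    pos_i = pos_i, pos_j = pos_j,
    region_i = ids[pos_i], region_j = ids[pos_j]
  )
}

# Coerce a features object (tibble/data.frame with a `subject` column, or a
# numeric matrix with rownames) into a numeric matrix aligned to `subjects`.
.feature_matrix <- function(features, subjects) {
  if (is.matrix(features)) {
    X <- features
    if (is.null(rownames(X))) {
      if (nrow(X) != length(subjects)) {
        stop("feature matrix has ", nrow(X), " rows but ", length(subjects),
             " subjects were supplied", call. = FALSE)
      }
      rownames(X) <- subjects
    }
  } else {
    df <- as.data.frame(features)
    if (!"subject" %in% names(df)) {
      stop("features must contain a `subject` column", call. = FALSE)
    }
    X <- as.matrix(df[setdiff(names(df), "subject")])
    rownames(X) <- df$subject
  }
  missing_ids <- setdiff(subjects, rownames(X))
  extra_ids <- setdiff(rownames(X), subjects)
  if (length(missing_ids) || length(extra_ids)) {
    stop("subject ids disagree between features and phenotypes; missing: [",
         paste(missing_ids, collapse = ", "), "]; unmatched: [",
         paste(extra_ids, collapse = ", "), "]", call. = FALSE)
  }
  X <- X[subjects, , drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  X
}

.assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}
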