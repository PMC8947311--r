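# The nearest-neighbor index (NNI): the synthesized seventh feature. For a
# query vector in the normalized, severity-aligned unit cube, the NNI is the
# fraction of glaucoma-labeled cases among the k nearest reference cases.

# Deterministic neighbor ordering: by distance, then by the lexicographic
# feature vector of the candidate row, then by label. Independent of the
# row order of the reference, so permuting the reference never changes an NNI.
.neighbor_order <- function(d, x, label) {
  do.call(order, c(list(d), lapply(seq_len(ncol(x)), function(j) x[, j]),
                   list(label)))
}

.row_distances <- function(query, x, metric) {
  if (metric == "euclidean") {
    sqrt(colSums((t(x) - query)^2))
  } else {
    colSums(abs(t(x) - query))
  }
}

#' Compute the nearest-neighbor index for a query vector
#'
#' Finds the `k` nearest reference cases to `query` (Euclidean distance in the
#' normalized-reversed feature space by default) and returns the fraction of
#' them labeled glaucoma, a value in `{0, 1/k, ..., 1}`. Ties at the k-th
#' distance are resolved deterministically by the candidate's feature vector
#' and label, so the result never depends on reference row order.
#'
#' @param query Numeric vector of length 6 in `[0, 1]` (canonical feature
#'   order), e.g. one row of [transform_records()].
#' @param reference An [reference_dataset()].
#' @param k Neighbor count (default 5).
#' @param exclude_row Optional row index of `query` inside the reference; that
#'   row is removed before the neighbor search (leave-one-out). Use when
#'   scoring a case that is itself part of the reference.
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return The NNI, a single number in `[0, 1]`.
#' @export
compute_nni <- function(query, reference, k = 5L, exclude_row = NULL,
                        metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(inherits(reference, "igri_reference"))
  query <- as.numeric(query)
  if (length(query) != 6 || any(!is.finite(query)) ||
      any(query < 0 | query > 1)) {
    stop("query must be a length-6 vector in [0, 1]")
  }
  x <- reference$x
  label <- reference$label
  if (!is.null(exclude_row)) {
    keep <- setdiff(seq_len(nrow(x)), exclude_row)
    x <- x[keep, , drop = FALSE]
    label <- label[keep]
  }
  k <- as.integer(k)
  if (nrow(x) < k) {
    stop("reference has ", nrow(x), " usable rows but k = ", k)
  }
  d <- .row_distances(query, x, metric)
  dk <- sort(d, partial = k)[k]
  cand <- which(d <= dk)
  if (length(cand) > k) {   # ties at the k-th distance: deterministic cut
    ord <- .neighbor_order(d[cand], x[cand, , drop = FALSE], label[cand])
    cand <- cand[ord[seq_len(k)]]
  }
  sum(label[cand] == 1L) / k
}

#' Leave-one-out NNI profile of a reference dataset
#'
#' Computes the NNI of every reference row against the remaining rows
#' (self excluded), returning values with their labels -- the per-group
#' distributions behind a boxplot comparison of NNI between the normal and
#' glaucoma groups.
#'
#' @inheritParams compute_nni
#' @return Data frame with columns `nni` and `label`, one row per reference
#'   row, in reference order.
#' @export
nni_profile <- function(reference, k = 5L,
                        metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(inherits(reference, "igri_reference"))
  k <- as.integer(k)
  n <- nrow(reference$x)
  if (n < k + 1L) stop("reference needs at least k + 1 rows for leave-one-out")
  nni <- vapply(seq_len(n), function(i) {
    compute_nni(reference$x[i, ], reference, k = k, exclude_row = i,
                metric = metric)
  }, numeric(1))
  data.frame(nni = nni, label = reference$label)
}

# Batch NNI for a matrix of query rows (not themselves in the reference).
.compute_nni_matrix <- function(xq, reference, k, metric = "euclidean") {
  vapply(seq_len(nrow(xq)), function(i) {
    compute_nni(xq[i, ], reference, k = k, metric = metric)
  }, numeric(1))
}
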