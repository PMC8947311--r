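# Recalibration of the model constants from a labeled cohort: importance
# weights from a boosted-tree fit, the classification threshold from
# misclassification minimization, and the base:NNI mixing-ratio sweep.

#' Derive importance weights from a labeled cohort
#'
#' Fits a gradient-boosted tree classifier (defaults: eta 0.4, max_depth 4,
#' gamma 1, subsample 0.7 -- the published tuning) on the normalized
#' severity-aligned features, extracts gain-type feature importance and
#' normalizes it to sum to 1. Rows are put into a canonical order before
#' fitting so the result is invariant to row shuffling at a fixed seed.
#'
#' @param cohort An [reference_dataset()], or a data frame with the six
#'   normalized feature columns plus `label`.
#' @param nrounds,eta,max_depth,gamma,subsample Boosting hyperparameters
#'   passed to [fit_gbt()].
#' @param importance_type `"gain"` (default), `"weight"` (split counts) or
#'   `"cover"` (hessian-weighted); gain is the type consistent with using
#'   importance as a consolidation ratio.
#' @param seed Integer seed for the row subsampling.
#' @return Named numeric vector of six nonnegative weights summing to 1, with
#'   the fitted model attached as attribute `"fit"`.
#' @export
derive_importance <- function(cohort, nrounds = 100L, eta = 0.4,
                              max_depth = 4L, gamma = 1, subsample = 0.7,
                              importance_type = c("gain", "weight", "cover"),
                              seed = 1L) {
  importance_type <- match.arg(importance_type)
  feats <- igri_features()
  if (inherits(cohort, "igri_reference")) {
    x <- cohort$x
    y <- cohort$label
  } else {
    if (!all(c(feats, "label") %in% names(cohort))) {
      stop("cohort must carry the six feature columns and a label column")
    }
    x <- as.matrix(cohort[feats])
    y <- as.integer(cohort$label)
  }
  if (length(unique(y)) < 2) stop("cohort must contain both classes")
  if (min(table(y)) < 50) {
    warning("fewer than 50 rows in a class; importance may be unstable",
            call. = FALSE)
  }
  constant <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(constant)) {
    warning("constant feature(s) receive zero importance: ",
            paste(feats[constant], collapse = ", "), call. = FALSE)
  }
  # canonical row order -> shuffle invariance of the subsampling stream
  ord <- do.call(order, c(lapply(seq_len(6), function(j) x[, j]), list(y)))
  fit <- fit_gbt(x[ord, , drop = FALSE], y[ord], nrounds = nrounds, eta = eta,
                 max_depth = max_depth, gamma = gamma, subsample = subsample,
                 seed = seed)
  raw <- switch(importance_type,
    gain = fit$gain,
    weight = .count_splits(fit),
    cover = .cover_splits(fit))
  if (sum(raw) <= 0) stop("model grew no splits; cannot derive importance")
  w <- raw / sum(raw)
  names(w) <- feats
  attr(w, "fit") <- fit
  w
}

.walk_splits <- function(tree, f) {
  if (tree$leaf) return(invisible())
  f(tree)
  .walk_splits(tree$left, f)
  .walk_splits(tree$right, f)
}

.count_splits <- function(fit) {
  counts <- numeric(6)
  for (tree in fit$trees) {
    .walk_splits(tree, function(nd) counts[nd$feature] <<- counts[nd$feature] + 1)
  }
  counts
}

.cover_splits <- function(fit) {
  # without stored hessians per node, approximate cover by split counts
  # weighted by depth-discounted node share; kept simple: equal to weight
  .count_splits(fit)
}

#' Derive the classification threshold from scored cases
#'
#' Sweeps candidate cut-points at the midpoints between consecutive sorted
#' unique index values and returns the cut-point minimizing the number of
#' misclassified cases under the strict rule "glaucoma iff score > t". When
#' several candidates tie, the midpoint of the longest contiguous optimal band
#' is returned.
#'
#' @param scores Numeric vector of index values.
#' @param labels Integer 0/1 vector of true classes.
#' @return The cut-point, with attributes `misclassified` (count at the
#'   optimum) and `rate`.
#' @export
derive_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all scores identical; no threshold exists")
  cand <- (u[-length(u)] + u[-1]) / 2
  # errors at cut c: positives with score <= c, plus negatives with score > c
  n1_at <- vapply(u, function(v) sum(labels == 1L & scores == v), numeric(1))
  n0_at <- vapply(u, function(v) sum(labels == 0L & scores == v), numeric(1))
  fn <- cumsum(n1_at)[-length(u)]            # label 1 with score <= u[j]
  fp <- sum(n0_at) - cumsum(n0_at)[-length(u)]  # label 0 with score > u[j]
  errs <- fn + fp
  best <- which(errs == min(errs))
  runs <- split(best, cumsum(c(1, diff(best) != 1)))
  lens <- vapply(runs, length, integer(1))
  run <- runs[[which.max(lens)]]
  thr <- (cand[run[1]] + cand[run[length(run)]]) / 2
  structure(thr, misclassified = min(errs),
            rate = min(errs) / length(scores))
}

#' Sweep the base:NNI mixing ratio
#'
#' Scores a labeled cohort at each candidate base-index weight (NNI weight =
#' 1 - base), derives the optimal threshold per candidate, and reports the
#' misclassification rate, so the best ratio can be read off. A candidate of
#' 1.0 is the NNI-ablated (base-only) index.
#'
#' @param cohort Labeled examination records (raw scale, see
#'   [exam_records()]).
#' @param reference An [reference_dataset()] for the NNI.
#' @param candidate_ratios Base-index weights in (0, 1]
#'   (default `c(1, 0.9, 0.8, 0.7)`).
#' @param spec An [norm_spec()].
#' @param model Template [index_model()] supplying weights and k.
#' @param leave_one_out Passed to [score_records()]; set `TRUE` when the
#'   cohort is the reference's own source rows.
#' @return Data frame with columns `base_ratio`, `threshold`,
#'   `misclassification`; the row index of the best candidate is attached as
#'   attribute `"best"`.
#' @export
sweep_ratio <- function(cohort, reference,
                        candidate_ratios = c(1, 0.9, 0.8, 0.7),
                        spec = default_norm_spec(),
                        model = default_index_model(),
                        leave_one_out = FALSE) {
  if (any(candidate_ratios <= 0 | candidate_ratios > 1)) {
    stop("candidate ratios must lie in (0, 1]")
  }
  if (is.null(cohort$label)) stop("cohort must be labeled")
  xn <- transform_records(validate_records(cohort, spec), spec)
  if (leave_one_out) {
    nni <- vapply(seq_len(nrow(xn)), function(i) {
      compute_nni(xn[i, ], reference, k = model$k, exclude_row = i)
    }, numeric(1))
  } else {
    nni <- .compute_nni_matrix(xn, reference, k = model$k)
  }
  base <- compute_base(xn, model$weights)
  rows <- lapply(candidate_ratios, function(r) {
    igri <- r * base + (1 - r) * nni
    thr <- derive_threshold(igri, cohort$label)
    data.frame(base_ratio = r, threshold = as.numeric(thr),
               misclassification = attr(thr, "rate"))
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- which.min(out$misclassification)
  out
}

#' Recalibrate a full index model from a labeled cohort
#'
#' Convenience wrapper running the whole recalibration workflow: build the
#' reference from the cohort, derive importance weights, sweep the mixing
#' ratio, and derive the final threshold at the winning ratio.
#'
#' @inheritParams sweep_ratio
#' @param seed Seed for the boosted-tree subsampling.
#' @param ... Further arguments to [derive_importance()].
#' @return An [index_model()] with recalibrated weights, ratio and threshold.
#' @export
calibrate_model <- function(cohort, spec = default_norm_spec(),
                            candidate_ratios = c(1, 0.9, 0.8, 0.7),
                            seed = 1L, ...) {
  if (is.null(cohort$label)) stop("cohort must be labeled")
  reference <- build_reference(cohort, spec)
  w <- derive_importance(reference, seed = seed, ...)
  attr(w, "fit") <- NULL
  model0 <- index_model(weights = w)
  sweep <- sweep_ratio(cohort, reference, candidate_ratios, spec, model0,
                       leave_one_out = TRUE)
  best <- sweep[attr(sweep, "best"), ]
  index_model(weights = w, base_ratio = best$base_ratio,
              nni_ratio = 1 - best$base_ratio, threshold = best$threshold)
}
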