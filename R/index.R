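# The index proper: weighted base score, convex combination with the NNI,
# threshold classification, and MD-based severity staging.

#' Base index from a normalized feature vector
#'
#' The importance-weighted sum of the six severity-aligned feature values:
#' `sum(vector * weights)`, with weights summing to 1 so the result stays in
#' `[0, 1]`.
#'
#' @param vector Numeric vector (length 6) or matrix (6 columns) of values in
#'   `[0, 1]`, canonical feature order.
#' @param weights Named importance weights summing to 1 (default: published).
#' @return Numeric value (or vector, for matrix input) in `[0, 1]`.
#' @examples
#' compute_base(c(0.5386, 0.4667, 0.6889, 0.7231, 0.6889, 0.25))  # 0.5971
#' @export
compute_base <- function(vector, weights = .DEFAULT_WEIGHTS) {
  feats <- igri_features()
  if (!all(feats %in% names(weights))) stop("weights must name all features")
  weights <- weights[feats]
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  if (is.matrix(vector)) {
    if (!is.null(colnames(vector))) vector <- vector[, feats, drop = FALSE]
    as.numeric(vector %*% weights)
  } else {
    if (length(vector) != 6) stop("vector must have 6 entries")
    if (!is.null(names(vector))) vector <- vector[feats]
    sum(vector * weights)
  }
}

#' Final index from base and NNI
#'
#' Convex combination `base_ratio * base + nni_ratio * nni` (published ratio
#' 0.8:0.2).
#'
#' @param base,nni Values in `[0, 1]` (vectorized).
#' @param model An [index_model()] supplying the mixing ratio.
#' @return The final index in `[0, 1]`.
#' @examples
#' compute_igri(0.5971, 1.0)  # 0.678 at 3 decimals
#' @export
compute_igri <- function(base, nni, model = default_index_model()) {
  if (abs(model$base_ratio + model$nni_ratio - 1) > 1e-9) {
    stop("mixing ratios must sum to 1")
  }
  model$base_ratio * base + model$nni_ratio * nni
}

#' Classify an index value
#'
#' A case is classified glaucoma iff its index is strictly greater than the
#' threshold (published cut-point 0.36); a value exactly at the threshold is
#' classified normal.
#'
#' @param igri Numeric vector of index values in `[0, 1]`.
#' @param threshold Cut-point in (0, 1).
#' @return Integer vector, 1 = glaucoma, 0 = normal.
#' @export
classify_igri <- function(igri, threshold = .DEFAULT_THRESHOLD) {
  as.integer(igri > threshold)
}

#' Stage glaucoma severity by mean deviation
#'
#' Within cases classified as glaucoma, assigns a progression stage from the
#' visual-field mean deviation: `advanced` below the lower boundary (default
#' MD < -12 dB), `intermediate` on the closed interval between the boundaries
#' (default -12 to -5 dB), `early` above (default MD > -5 dB). Cases
#' classified normal receive stage `"normal"`.
#'
#' @param md Numeric vector of raw MD values (dB).
#' @param predicted_class Integer 0/1 vector from [classify_igri()]; when
#'   omitted every case is staged as glaucoma.
#' @param bins Named numeric `c(intermediate =, advanced =)` MD boundaries.
#' @return Factor with levels normal < early < intermediate < advanced.
#' @examples
#' stage_by_md(c(-2, -8, -13))
#' @export
stage_by_md <- function(md, predicted_class = NULL,
                        bins = .DEFAULT_STAGING_BINS) {
  if (bins[["advanced"]] >= bins[["intermediate"]]) {
    stop("staging bins must satisfy advanced < intermediate")
  }
  stage <- ifelse(md < bins[["advanced"]], "advanced",
                  ifelse(md <= bins[["intermediate"]], "intermediate",
                         "early"))
  if (!is.null(predicted_class)) {
    stage[predicted_class == 0L] <- "normal"
  }
  factor(stage, levels = .STAGE_LEVELS, ordered = TRUE)
}

#' Score examination records end to end
#'
#' Runs the full pipeline per record: normalization and reversal into the
#' severity-aligned unit cube, NNI against the reference dataset, weighted
#' base index, final index, threshold classification, border-band flag and MD
#' stage.
#'
#' @param records Data frame of examination records (see [exam_records()]).
#' @param spec An [norm_spec()].
#' @param reference An [reference_dataset()] for the NNI lookup.
#' @param model An [index_model()].
#' @param leave_one_out If `TRUE`, records are assumed to be (in order) the
#'   very rows the reference was built from, and each row is excluded from its
#'   own neighbor search. Use when re-scoring the reference cohort itself.
#' @param metric Distance metric for the NNI.
#' @return Data frame: the six raw features, the six normalized values
#'   (`*_norm`), `nni`, `base`, `igri`, `predicted_class`, `border` (inside
#'   threshold +/- `model$border_margin`), `stage`, plus `label` when present.
#' @examples
#' \dontrun{
#' ref <- default_reference(seed = 1)
#' score_records(exam_records(9.54, -7.84, 56, 54, 48, 11), reference = ref)
#' }
#' @export
score_records <- function(records, spec = default_norm_spec(),
                          reference, model = default_index_model(),
                          leave_one_out = FALSE,
                          metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  records <- validate_records(records, spec)
  xn <- transform_records(records, spec)
  if (leave_one_out) {
    if (nrow(xn) != nrow(reference$x)) {
      stop("leave_one_out requires records to match the reference rows")
    }
    nni <- vapply(seq_len(nrow(xn)), function(i) {
      compute_nni(xn[i, ], reference, k = model$k, exclude_row = i,
                  metric = metric)
    }, numeric(1))
  } else {
    nni <- .compute_nni_matrix(xn, reference, k = model$k, metric = metric)
  }
  base <- compute_base(xn, model$weights)
  igri <- compute_igri(base, nni, model)
  cls <- classify_igri(igri, model$threshold)
  out <- as.data.frame(records[igri_features()])
  norm_df <- as.data.frame(xn)
  names(norm_df) <- paste0(igri_features(), "_norm")
  out <- cbind(out, norm_df)
  out$nni <- nni
  out$base <- base
  out$igri <- igri
  out$predicted_class <- cls
  out$border <- abs(igri - model$threshold) <= model$border_margin
  out$stage <- stage_by_md(records$MD, cls, model$staging_bins)
  if (!is.null(records$label)) out$label <- records$label
  rownames(out) <- NULL
  out
}
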