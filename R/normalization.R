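# Min-max normalization with clipping, directional reversal, and the full
# record transform into the severity-aligned unit cube.

#' Min-max normalize a feature value
#'
#' Maps `value` to `(value - min) / (max - min)`, clipped to `[0, 1]` so that
#' out-of-range measurements saturate rather than leave the unit interval.
#'
#' @param value Numeric vector of raw measurements.
#' @param bounds Length-2 numeric `c(min, max)`, `min < max`.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' normalize_feature(9.54, c(0.95, 16.9))   # 0.5386 to 4 decimals
#' @export
normalize_feature <- function(value, bounds) {
  if (length(bounds) != 2 || !all(is.finite(bounds)) || bounds[1] >= bounds[2]) {
    stop("bounds must be finite with min < max")
  }
  pmin(pmax((value - bounds[1]) / (bounds[2] - bounds[1]), 0), 1)
}

#' Reverse a unit-interval value
#'
#' Computes `1 - x`, used to flip features where a *lower* raw value means
#' more severe disease (MD, RNFL thickness) onto the common severity scale.
#'
#' @param x Numeric vector in `[0, 1]`.
#' @return `1 - x`.
#' @export
reverse_unit <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("values must lie in [0, 1]")
  1 - x
}

#' Transform records into the severity-aligned unit cube
#'
#' Applies min-max normalization per feature followed by reversal of the
#' features in `spec$reversed`, in the canonical column order
#' (PSD, MD, RNFL_S, RNFL_I, RNFL_T, IOP). After the transform every
#' coordinate is in `[0, 1]` and higher always means more severe.
#'
#' @param records Data frame of examination records (see [exam_records()]).
#' @param spec An [norm_spec()]; defaults to the published bounds.
#' @return Numeric matrix with one row per record and the six feature columns.
#' @examples
#' r <- exam_records(9.54, -7.84, 56, 54, 48, 11)
#' transform_records(r)
#' @export
transform_records <- function(records, spec = default_norm_spec()) {
  feats <- igri_features()
  if (is.numeric(records) && is.null(dim(records))) {
    records <- as.data.frame(as.list(stats::setNames(records[seq_len(6)], feats)))
  }
  out <- matrix(NA_real_, nrow = nrow(records), ncol = 6,
                dimnames = list(NULL, feats))
  for (f in feats) {
    v <- normalize_feature(records[[f]], spec$bounds[[f]])
    if (f %in% spec$reversed) v <- reverse_unit(v)
    out[, f] <- v
  }
  out
}

#' Fit normalization bounds from a cohort (non-canonical helper)
#'
#' Estimates per-feature (min, max) bounds as quantiles of the observed
#' distribution, trimming a small tail fraction on each side as an outlier
#' rule. This is a convenience for user cohorts only; the published bounds
#' from [default_norm_spec()] remain the canonical scaling and are used by
#' default everywhere.
#'
#' @param records Data frame of examination records.
#' @param trim Tail probability excluded on each side (default 0.005).
#' @param reversed Reversed-feature set to attach (default: published set).
#' @return An `igri_norm_spec`.
#' @export
fit_norm_spec <- function(records, trim = 0.005,
                          reversed = .DEFAULT_REVERSED) {
  stopifnot(trim >= 0, trim < 0.5)
  bounds <- lapply(igri_features(), function(f) {
    unname(stats::quantile(records[[f]], c(trim, 1 - trim), names = FALSE))
  })
  names(bounds) <- igri_features()
  norm_spec(bounds, reversed)
}
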