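# Domain types shared by every module: examination records, the normalization
# specification, the index model and the reference dataset.

#' Construct a table of examination records
#'
#' An examination record is one eye's measurement of the six index features:
#' PSD (dB), MD (dB), RNFL_S/RNFL_I/RNFL_T (um) and IOP (mmHg), optionally
#' with a binary class label (0 normal / 1 glaucoma).
#'
#' @param psd,md,rnfl_s,rnfl_i,rnfl_t,iop Numeric vectors of equal length.
#' @param label Optional integer vector of 0/1 class labels (NA allowed).
#' @param validate Run [validate_records()] on the result (default `TRUE`).
#' @return A `data.frame` with columns `PSD, MD, RNFL_S, RNFL_I, RNFL_T, IOP`
#'   and, when labels are given, `label`.
#' @examples
#' exam_records(psd = 9.54, md = -7.84, rnfl_s = 56, rnfl_i = 54,
#'              rnfl_t = 48, iop = 11)
#' @export
exam_records <- function(psd, md, rnfl_s, rnfl_i, rnfl_t, iop,
                         label = NULL, validate = TRUE) {
  df <- data.frame(PSD = as.numeric(psd), MD = as.numeric(md),
                   RNFL_S = as.numeric(rnfl_s), RNFL_I = as.numeric(rnfl_i),
                   RNFL_T = as.numeric(rnfl_t), IOP = as.numeric(iop))
  if (!is.null(label)) {
    lab <- as.integer(label)
    bad <- !is.na(lab) & !(lab %in% c(0L, 1L))
    if (any(bad)) stop("labels must be 0 (normal) or 1 (glaucoma)")
    df$label <- lab
  }
  if (validate) validate_records(df) else df
}

#' Validate examination records
#'
#' Checks that every record carries all six features as finite numbers inside
#' loose physiological plausibility bounds (e.g. IOP in 1--80 mmHg, MD in -40
#' to +10 dB). Values that are plausible but fall outside the normalization
#' bounds raise a warning only -- they will saturate at 0 or 1 during
#' normalization, never be altered here.
#'
#' @param records Data frame with the six feature columns (see
#'   [exam_records()]); extra columns are carried through untouched.
#' @param spec A [norm_spec()] whose bounds define the warning range.
#' @return `records`, invisibly unchanged, with feature columns coerced to
#'   numeric and reordered to the canonical order first.
#' @export
validate_records <- function(records, spec = default_norm_spec()) {
  feats <- igri_features()
  if (!is.data.frame(records)) stop("records must be a data.frame")
  missing_cols <- setdiff(feats, names(records))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (f in feats) {
    v <- records[[f]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
      if (any(is.na(v) & !is.na(records[[f]]))) {
        stop("non-numeric value(s) in feature ", f)
      }
      records[[f]] <- v
    }
    bad <- !is.finite(records[[f]])
    if (any(bad)) {
      stop("missing or non-finite value(s) in feature ", f,
           " (rows ", paste(utils::head(which(bad), 5), collapse = ", "), ")")
    }
    pl <- .PLAUSIBLE_RANGE[[f]]
    impl <- records[[f]] < pl[1] | records[[f]] > pl[2]
    if (any(impl)) {
      stop("implausible ", f, " value(s) outside [", pl[1], ", ", pl[2], "]",
           " (rows ", paste(utils::head(which(impl), 5), collapse = ", "), ")")
    }
    b <- spec$bounds[[f]]
    oob <- records[[f]] < b[1] | records[[f]] > b[2]
    if (any(oob)) {
      warning(sum(oob), " value(s) of ", f, " outside normalization range [",
              b[1], ", ", b[2], "]; they will be clipped", call. = FALSE)
    }
  }
  extra <- setdiff(names(records), feats)
  records[, c(feats, extra), drop = FALSE]
}

#' Normalization specification
#'
#' Per-feature (min, max) scaling bounds plus the set of features whose
#' normalized value is reversed (`1 - x`) so that all six coordinates are
#' severity-aligned (higher = more severe).
#'
#' @param bounds Named list of length-2 numeric `c(min, max)` vectors, one per
#'   feature, `min < max`.
#' @param reversed Character vector naming the reversed features.
#' @return An object of class `igri_norm_spec`.
#' @seealso [default_norm_spec()] for the published bounds.
#' @export
norm_spec <- function(bounds, reversed = .DEFAULT_REVERSED) {
  feats <- igri_features()
  if (!all(feats %in% names(bounds))) {
    stop("bounds must name all features: ", paste(feats, collapse = ", "))
  }
  bounds <- bounds[feats]
  for (f in feats) {
    b <- bounds[[f]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("bounds for ", f, " must be finite with min < max")
    }
  }
  if (!all(reversed %in% feats)) {
    stop("unknown reversed feature(s): ",
         paste(setdiff(reversed, feats), collapse = ", "))
  }
  structure(list(bounds = bounds, reversed = unique(reversed)),
            class = "igri_norm_spec")
}

#' Published default normalization specification
#'
#' Bounds: PSD (0.95, 16.9) dB, MD (-24.1, 6.39) dB, RNFL_S (6, 172) um,
#' RNFL_I (0, 195) um, RNFL_T (20, 110) um, IOP (5, 29) mmHg. Reversed
#' features: MD and the three RNFL sectors.
#'
#' @return An `igri_norm_spec`.
#' @export
default_norm_spec <- function() {
  norm_spec(.DEFAULT_BOUNDS, .DEFAULT_REVERSED)
}

#' Index model configuration
#'
#' Holds everything needed to turn a normalized feature vector and an NNI into
#' a final index value, class and stage: the per-feature importance weights,
#' the base:NNI mixing ratio, the classification threshold, the neighbor count
#' and the MD staging bins.
#'
#' @param weights Named nonnegative numeric vector over the six features,
#'   summing to 1 (tolerance 1e-6).
#' @param base_ratio,nni_ratio Convex mixing weights on the base index and the
#'   NNI; must sum to 1.
#' @param threshold Classification cut-point in (0, 1); a case is classified
#'   glaucoma iff its index is strictly greater.
#' @param k Neighbor count for the NNI.
#' @param staging_bins Named numeric `c(intermediate =, advanced =)` MD
#'   boundaries in dB: advanced below `advanced`, intermediate on
#'   `[advanced, intermediate]`, early above.
#' @param border_margin Half-width of the reported border band around the
#'   threshold (presentation only; does not affect classification).
#' @return An object of class `igri_model`.
#' @seealso [default_index_model()] for the published constants.
#' @export
index_model <- function(weights = .DEFAULT_WEIGHTS,
                        base_ratio = .DEFAULT_BASE_RATIO,
                        nni_ratio = .DEFAULT_NNI_RATIO,
                        threshold = .DEFAULT_THRESHOLD,
                        k = .DEFAULT_K,
                        staging_bins = .DEFAULT_STAGING_BINS,
                        border_margin = 0.05) {
  feats <- igri_features()
  if (!all(feats %in% names(weights))) {
    stop("weights must name all features: ", paste(feats, collapse = ", "))
  }
  weights <- weights[feats]
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  }
  if (abs(base_ratio + nni_ratio - 1) > 1e-9) {
    stop("base_ratio + nni_ratio must equal 1")
  }
  if (base_ratio < 0 || nni_ratio < 0) stop("mixing ratios must be in [0, 1]")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  if (!all(c("intermediate", "advanced") %in% names(staging_bins)) ||
      staging_bins[["advanced"]] >= staging_bins[["intermediate"]]) {
    stop("staging_bins must give advanced < intermediate MD boundaries")
  }
  structure(list(weights = weights, base_ratio = base_ratio,
                 nni_ratio = nni_ratio, threshold = threshold, k = k,
                 staging_bins = staging_bins[c("intermediate", "advanced")],
                 border_margin = border_margin),
            class = "igri_model")
}

#' Published default index model
#'
#' Importance weights (PSD 0.27, MD 0.14, RNFL_S 0.11, RNFL_I 0.31,
#' RNFL_T 0.10, IOP 0.07), base:NNI ratio 0.8:0.2, classification threshold
#' 0.36, k = 5 neighbors, and MD staging at -5 / -12 dB.
#'
#' @return An `igri_model`.
#' @export
default_index_model <- function() index_model()

#' Reference dataset for NNI lookup
#'
#' A labeled cohort already mapped into the normalized, severity-aligned unit
#' cube; nearest-neighbor queries for the NNI run against it.
#'
#' @param x Numeric matrix (rows = cases) with the six feature columns, all
#'   entries in `[0, 1]`.
#' @param label Integer 0/1 vector, one per row; both classes must appear.
#' @param provenance `"synthetic"` or `"user-supplied"`.
#' @return An object of class `igri_reference`.
#' @export
reference_dataset <- function(x, label,
                              provenance = c("user-supplied", "synthetic")) {
  provenance <- match.arg(provenance)
  x <- as.matrix(x)
  feats <- igri_features()
  if (ncol(x) != 6) stop("reference matrix must have 6 columns")
  if (!is.null(colnames(x))) {
    if (!all(feats %in% colnames(x))) {
      stop("reference columns must be the six features")
    }
    x <- x[, feats, drop = FALSE]
  } else {
    colnames(x) <- feats
  }
  if (nrow(x) == 0) stop("reference dataset is empty")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("reference entries must all lie in [0, 1]")
  }
  label <- as.integer(label)
  if (length(label) != nrow(x) || any(is.na(label)) ||
      !all(label %in% c(0L, 1L))) {
    stop("label must be a 0/1 vector with one entry per reference row")
  }
  if (length(unique(label)) < 2) {
    stop("reference dataset must contain both classes")
  }
  structure(list(x = x, label = label, provenance = provenance),
            class = "igri_reference")
}

#' @export
print.igri_norm_spec <- function(x, ...) {
  cat("<igri_norm_spec>\n")
  b <- do.call(rbind, x$bounds)
  colnames(b) <- c("min", "max")
  print(cbind(as.data.frame(b),
              reversed = rownames(b) %in% x$reversed))
  invisible(x)
}

#' @export
print.igri_model <- function(x, ...) {
  cat("<igri_model>\n  weights: ",
      paste(sprintf("%s=%.3g", names(x$weights), x$weights), collapse = " "),
      "\n  base:nni = ", x$base_ratio, ":", x$nni_ratio,
      "  threshold = ", x$threshold, "  k = ", x$k, "\n",
      "  staging (MD dB): intermediate <= ", x$staging_bins[["intermediate"]],
      ", advanced < ", x$staging_bins[["advanced"]], "\n", sep = "")
  invisible(x)
}

#' @export
print.igri_reference <- function(x, ...) {
  cat("<igri_reference> ", nrow(x$x), " cases (",
      sum(x$label == 1), " glaucoma / ", sum(x$label == 0), " normal), ",
      x$provenance, "\n", sep = "")
  invisible(x)
}
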