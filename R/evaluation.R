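# Evaluation surface: misclassification, group separation, NNI ablation and
# the MD-vs-index correlation.

#' Misclassification rate at a fixed threshold
#'
#' @param scores Numeric index values.
#' @param labels Integer 0/1 true classes.
#' @param threshold Cut-point (strict rule: glaucoma iff score > threshold).
#' @return Proportion of cases whose predicted class differs from the label.
#' @export
misclassification_rate <- function(scores, labels,
                                   threshold = .DEFAULT_THRESHOLD) {
  if (length(scores) == 0) stop("empty input")
  stopifnot(length(scores) == length(labels))
  mean(classify_igri(scores, threshold) != as.integer(labels))
}

#' Per-group summary with pairwise Welch tests
#'
#' @param scores Numeric index values.
#' @param groups Character/factor group membership, one per score.
#' @param pairs Optional list of length-2 character vectors naming group pairs
#'   to compare with a Welch two-sample t-test.
#' @return List with `summary` (group, n, mean, sd) and `tests` (group1,
#'   group2, statistic, df, p_value), `tests` being `NULL` when no pairs are
#'   requested.
#' @export
group_summary <- function(scores, groups, pairs = NULL) {
  stopifnot(length(scores) == length(groups))
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  summary <- data.frame(
    group = gl,
    n = vapply(gl, function(g) sum(groups == g), integer(1)),
    mean = vapply(gl, function(g) mean(scores[groups == g]), numeric(1)),
    sd = vapply(gl, function(g) stats::sd(scores[groups == g]), numeric(1)),
    row.names = NULL)
  tests <- NULL
  if (!is.null(pairs)) {
    tests <- do.call(rbind, lapply(pairs, function(p) {
      if (!all(p %in% gl)) {
        stop("unknown group name(s): ", paste(setdiff(p, gl), collapse = ", "))
      }
      a <- scores[groups == p[1]]; b <- scores[groups == p[2]]
      if (length(a) < 2 || length(b) < 2) {
        stop("need >= 2 rows per group for the test (", p[1], " vs ", p[2], ")")
      }
      tt <- stats::t.test(a, b)
      data.frame(group1 = p[1], group2 = p[2],
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
    }))
  }
  list(summary = summary, tests = tests)
}

#' Histogram overlap coefficient between the two class distributions
#'
#' Deterministic proxy for the overlap of the per-class index densities:
#' both classes are binned on a fixed grid over `[0, 1]` and the overlap is
#' the sum of per-bin minimum class proportions (1 = identical histograms,
#' 0 = disjoint support).
#'
#' @param scores Numeric values in `[0, 1]`.
#' @param labels Integer 0/1 classes.
#' @param bins Number of equal-width bins (default 50).
#' @return Overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(scores, labels, bins = 50L) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!any(labels == 0L) || !any(labels == 1L)) {
    stop("both classes must be present")
  }
  br <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(scores, br, rightmost.closed = TRUE), 1L),
              bins)
  p0 <- tabulate(idx[labels == 0L], bins) / sum(labels == 0L)
  p1 <- tabulate(idx[labels == 1L], bins) / sum(labels == 1L)
  sum(pmin(p0, p1))
}

#' NNI ablation report
#'
#' Scores a labeled cohort twice -- with the configured base:NNI mix and with
#' the NNI removed (base only) -- and reports, per variant, the optimal
#' in-sample threshold, its misclassification rate, and the class-histogram
#' overlap coefficient. The NNI earns its place if it lowers the overlap
#' and/or the misclassification.
#'
#' @param cohort Labeled examination records (raw scale).
#' @param reference An [reference_dataset()].
#' @param model An [index_model()].
#' @param spec An [norm_spec()].
#' @param leave_one_out Passed to the scorer; set `TRUE` when the cohort is
#'   the reference's own source.
#' @param bins Histogram bins for the overlap coefficient.
#' @return Data frame with rows `with_nni` and `base_only` and columns
#'   `threshold`, `misclassification`, `overlap`.
#' @export
ablation_nni <- function(cohort, reference, model = default_index_model(),
                         spec = default_norm_spec(), leave_one_out = FALSE,
                         bins = 50L) {
  if (is.null(cohort$label)) stop("cohort must be labeled")
  xn <- transform_records(suppressWarnings(validate_records(cohort, spec)),
                          spec)
  if (leave_one_out) {
    nni <- vapply(seq_len(nrow(xn)), function(i) {
      compute_nni(xn[i, ], reference, k = model$k, exclude_row = i)
    }, numeric(1))
  } else {
    nni <- .compute_nni_matrix(xn, reference, k = model$k)
  }
  base <- compute_base(xn, model$weights)
  variants <- list(with_nni = compute_igri(base, nni, model),
                   base_only = base)
  out <- do.call(rbind, lapply(names(variants), function(v) {
    s <- variants[[v]]
    thr <- derive_threshold(s, cohort$label)
    data.frame(variant = v, threshold = as.numeric(thr),
               misclassification = attr(thr, "rate"),
               overlap = overlap_coefficient(s, cohort$label, bins))
  }))
  rownames(out) <- out$variant
  out
}

#' Correlation between MD and the index in the glaucoma subset
#'
#' Pearson correlation between the raw visual-field mean deviation and the
#' final index over glaucoma-labeled cases. By construction the signed
#' correlation is negative (lower MD means higher severity, hence a higher
#' index); the absolute value is reported alongside for comparison with
#' magnitude-only statements.
#'
#' @param records Examination records; if a `label` column is present only
#'   rows with `label == 1` are used, otherwise all rows are treated as
#'   glaucoma.
#' @param scores Index values aligned with `records`.
#' @return List with `r` (signed), `abs_r` and `n`.
#' @export
md_correlation <- function(records, scores) {
  stopifnot(nrow(records) == length(scores))
  keep <- if (!is.null(records$label)) records$label == 1L else
    rep(TRUE, nrow(records))
  md <- records$MD[keep]
  s <- scores[keep]
  if (length(md) < 3) stop("need >= 3 glaucoma rows")
  if (stats::sd(md) == 0 || stats::sd(s) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(md, s)
  list(r = r, abs_r = abs(r), n = length(md))
}

#' Full evaluation report for a labeled cohort
#'
#' Bundles the evaluation surface into one list: misclassification at the
#' model threshold, normal/glaucoma group summary with a Welch test, the NNI
#' ablation, the MD correlation, and per-stage index means.
#'
#' @inheritParams ablation_nni
#' @return A list; `in_sample` records whether the cohort is also the
#'   reference source (`leave_one_out = TRUE`), i.e. whether the numbers are
#'   in-sample.
#' @export
evaluate_cohort <- function(cohort, reference, model = default_index_model(),
                            spec = default_norm_spec(),
                            leave_one_out = FALSE) {
  if (is.null(cohort$label)) stop("cohort must be labeled")
  scored <- suppressWarnings(
    score_records(cohort, spec, reference, model,
                  leave_one_out = leave_one_out))
  grp <- ifelse(cohort$label == 1L, "glaucoma", "normal")
  gs <- group_summary(scored$igri, grp, pairs = list(c("glaucoma", "normal")))
  stage_grp <- as.character(stage_by_md(cohort$MD, cohort$label,
                                        model$staging_bins))
  stage_means <- group_summary(scored$igri, stage_grp)$summary
  list(
    n = nrow(cohort),
    in_sample = leave_one_out,
    threshold = model$threshold,
    misclassification = misclassification_rate(scored$igri, cohort$label,
                                               model$threshold),
    groups = gs$summary,
    welch = gs$tests,
    ablation = ablation_nni(cohort, reference, model, spec, leave_one_out),
    md_correlation = md_correlation(cohort, scored$igri),
    stage_means = stage_means
  )
}
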