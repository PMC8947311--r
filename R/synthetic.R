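# Synthetic two-class examination cohorts. The study cohort (hospital records)
# has no public accession, so a seeded generator emulates its coarse
# structure: per-class truncated multivariate Gaussians over the six raw
# features, anchored to the published typical glaucoma/normal profiles, with
# class counts matching the published cohort (955 normal / 1349 glaucoma).

.ANCHOR_NORMAL   <- c(PSD = 1.43, MD = -1.49, RNFL_S = 125, RNFL_I = 140,
                      RNFL_T = 63, IOP = 13)
.ANCHOR_GLAUCOMA <- c(PSD = 9.54, MD = -7.84, RNFL_S = 56, RNFL_I = 54,
                      RNFL_T = 48, IOP = 11)

.default_sds <- function() {
  r <- vapply(.DEFAULT_BOUNDS, function(b) b[2] - b[1], numeric(1))
  r / 4
}

.default_correlation <- function() {
  feats <- igri_features()
  R <- diag(6)
  dimnames(R) <- list(feats, feats)
  rnfl <- c("RNFL_S", "RNFL_I", "RNFL_T")
  R[rnfl, rnfl] <- 0.5
  diag(R) <- 1
  R["MD", rnfl] <- 0.4
  R[rnfl, "MD"] <- 0.4
  R
}

.default_truncation <- function(margin = 0.2) {
  feats <- igri_features()
  out <- lapply(feats, function(f) {
    b <- .DEFAULT_BOUNDS[[f]]
    ext <- margin * (b[2] - b[1])
    pl <- .PLAUSIBLE_RANGE[[f]]
    c(max(b[1] - ext, pl[1]), min(b[2] + ext, pl[2]))
  })
  names(out) <- feats
  out
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_normal,n_glaucoma Case counts per class (defaults 955 and 1349,
#'   the published cohort sizes).
#' @param mean_normal,mean_glaucoma Named per-class mean vectors of the six
#'   raw features; defaults are the published typical normal and glaucoma
#'   examination rows.
#' @param sds Named per-feature standard deviations; default one quarter of
#'   each feature's normalization range.
#' @param correlation 6x6 feature correlation matrix; default: 0.5 among the
#'   RNFL sectors, 0.4 between MD and each RNFL sector, 0 elsewhere.
#' @param truncation Named list of `c(lo, hi)` raw-scale truncation bounds;
#'   default: the normalization bounds extended by `margin` of the range on
#'   each side, clamped to physiological floors.
#' @param margin Extension fraction used by the default truncation.
#' @param separation Multiplier on the between-class mean difference: 1 keeps
#'   the anchors, 0 collapses both classes onto the pooled mean.
#' @param seed Integer seed.
#' @return Object of class `igri_cohort_config`.
#' @export
cohort_config <- function(n_normal = 955L, n_glaucoma = 1349L,
                          mean_normal = .ANCHOR_NORMAL,
                          mean_glaucoma = .ANCHOR_GLAUCOMA,
                          sds = .default_sds(),
                          correlation = .default_correlation(),
                          truncation = NULL, margin = 0.2,
                          separation = 1, seed = 1L) {
  feats <- igri_features()
  n_normal <- as.integer(n_normal); n_glaucoma <- as.integer(n_glaucoma)
  if (n_normal < 1 || n_glaucoma < 1) stop("class counts must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  mean_normal <- mean_normal[feats]; mean_glaucoma <- mean_glaucoma[feats]
  sds <- sds[feats]
  if (any(!is.finite(mean_normal)) || any(!is.finite(mean_glaucoma)) ||
      any(!is.finite(sds)) || any(sds <= 0)) {
    stop("means must be finite and sds positive for all six features")
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix must be positive semidefinite")
  if (is.null(truncation)) truncation <- .default_truncation(margin)
  truncation <- truncation[feats]
  pooled <- (mean_normal + mean_glaucoma) / 2
  m_n <- pooled + separation * (mean_normal - pooled)
  m_g <- pooled + separation * (mean_glaucoma - pooled)
  for (f in feats) {
    tr <- truncation[[f]]
    if (tr[1] >= tr[2]) stop("degenerate truncation bounds for ", f)
    for (m in c(m_n[f], m_g[f])) {
      if (m < tr[1] - 6 * sds[[f]] || m > tr[2] + 6 * sds[[f]]) {
        stop("truncation bounds for ", f, " exclude the class mean by > 6 SD")
      }
    }
  }
  structure(list(n_normal = n_normal, n_glaucoma = n_glaucoma,
                 mean_normal = m_n, mean_glaucoma = m_g, sds = sds,
                 correlation = correlation, truncation = truncation,
                 separation = separation, seed = as.integer(seed)),
            class = "igri_cohort_config")
}

# Rejection-sample n truncated MVN rows.
.rtmvnorm <- function(n, mean, Sigma, truncation) {
  feats <- igri_features()
  lo <- vapply(truncation, `[`, numeric(1), 1)
  hi <- vapply(truncation, `[`, numeric(1), 2)
  out <- matrix(NA_real_, nrow = 0, ncol = 6)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 1000L) stop("truncation bounds reject nearly all draws")
    m <- ceiling((n - nrow(out)) * 1.6) + 8L
    draw <- MASS::mvrnorm(m, mu = mean, Sigma = Sigma)
    keep <- rowSums(sweep(draw, 2, lo, `<`) | sweep(draw, 2, hi, `>`)) == 0
    out <- rbind(out, draw[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- feats
  out
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_normal` + `n_glaucoma` examination records from per-class
#' truncated multivariate Gaussians over the six raw features and shuffles
#' them under the configured seed. With the default configuration the class
#' differences run in the clinically expected directions: glaucoma cases have
#' higher PSD, more negative MD and thinner RNFL; the IOP difference is small
#' (many glaucoma cases in the emulated cohort are normal-tension).
#'
#' @param config An [cohort_config()].
#' @return Data frame of examination records with a `label` column
#'   (0 normal / 1 glaucoma), carrying attribute `provenance = "synthetic"`.
#' @examples
#' head(generate_cohort(cohort_config(n_normal = 5, n_glaucoma = 5)))
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "igri_cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  S <- diag(config$sds) %*% config$correlation %*% diag(config$sds)
  xg <- .rtmvnorm(config$n_glaucoma, config$mean_glaucoma, S,
                  config$truncation)
  xn <- .rtmvnorm(config$n_normal, config$mean_normal, S, config$truncation)
  df <- as.data.frame(rbind(xn, xg))
  df$label <- rep(c(0L, 1L), c(config$n_normal, config$n_glaucoma))
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provenance") <- "synthetic"
  df
}

#' Build a reference dataset from a labeled cohort
#'
#' Maps every cohort row into the normalized, severity-aligned unit cube and
#' attaches the labels, yielding the lookup population for the NNI.
#'
#' @param cohort Labeled examination records (raw scale).
#' @param spec An [norm_spec()].
#' @return An [reference_dataset()]; provenance is taken from the cohort's
#'   `provenance` attribute when present.
#' @export
build_reference <- function(cohort, spec = default_norm_spec()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("cohort must be a non-empty data.frame")
  }
  if (is.null(cohort$label)) stop("cohort must carry a label column")
  prov <- attr(cohort, "provenance")
  if (is.null(prov)) prov <- "user-supplied"
  xn <- transform_records(suppressWarnings(validate_records(cohort, spec)),
                          spec)
  reference_dataset(xn, cohort$label, provenance = prov)
}

#' Packaged default reference dataset
#'
#' The seeded default synthetic cohort (955 normal / 1349 glaucoma), built
#' into a reference dataset with the published normalization. Stands in for
#' the study's protected hospital reference population; absolute cohort-level
#' results computed against it are properties of the synthetic world, not of
#' the clinical data.
#'
#' @param seed Integer seed (default 1).
#' @return An [reference_dataset()].
#' @export
default_reference <- function(seed = 1L) {
  build_reference(generate_cohort(cohort_config(seed = seed)))
}

#' Cohort configuration with a planted importance profile
#'
#' Builds a diagonal-covariance configuration whose per-feature between-class
#' mean differences are proportional to a target weight profile (in units of
#' each feature's normalization range, severity-aligned sign), for
#' rank-recovery experiments on [derive_importance()].
#'
#' @param weights Target importance profile (default: published weights).
#' @param scale Overall effect-size multiplier; at 1, a feature with weight w
#'   has a standardized class difference of about 4w.
#' @param n_per_class Cases per class (default 300).
#' @param seed Integer seed.
#' @return An [cohort_config()].
#' @export
planted_cohort_config <- function(weights = .DEFAULT_WEIGHTS, scale = 1,
                                  n_per_class = 300L, seed = 1L) {
  feats <- igri_features()
  weights <- weights[feats]
  ranges <- vapply(.DEFAULT_BOUNDS, function(b) b[2] - b[1], numeric(1))
  centre <- vapply(.DEFAULT_BOUNDS, mean, numeric(1))
  severity_sign <- ifelse(feats %in% .DEFAULT_REVERSED, -1, 1)
  delta <- weights * scale * ranges * severity_sign / 2
  cohort_config(n_normal = n_per_class, n_glaucoma = n_per_class,
                mean_normal = centre - delta, mean_glaucoma = centre + delta,
                sds = ranges / 4, correlation = diag(6), seed = seed)
}
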