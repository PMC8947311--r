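# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, full sorts, direct formulas) and never call the code paths they
# check.

# The published typical examination rows (glaucoma / border / normal).
typical_rows <- function() {
  exam_records(
    psd = c(9.54, 2.29, 1.43),
    md = c(-7.84, -6.99, -1.49),
    rnfl_s = c(56, 94, 125),
    rnfl_i = c(54, 89, 140),
    rnfl_t = c(48, 77, 63),
    iop = c(11, 12, 13),
    label = c(1L, NA, 0L))
}

worked_example_record <- function() typical_rows()[1, ]

# Published normalization bounds as a plain list (restated independently of
# the package constants so a regression in the defaults is caught).
published_bounds <- function() {
  list(PSD = c(0.95, 16.9), MD = c(-24.1, 6.39), RNFL_S = c(6, 172),
       RNFL_I = c(0, 195), RNFL_T = c(20, 110), IOP = c(5, 29))
}

published_weights <- function() {
  c(PSD = 0.27, MD = 0.14, RNFL_S = 0.11, RNFL_I = 0.31, RNFL_T = 0.10,
    IOP = 0.07)
}

# Random unit-cube reference with both classes guaranteed.
random_reference <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 6), ncol = 6)
  label <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
  reference_dataset(x, label, provenance = "synthetic")
}

# Brute-force k-NN class-fraction oracle: all distances, full sort.
oracle_nni <- function(query, x, label, k, exclude = NULL) {
  idx <- setdiff(seq_len(nrow(x)), exclude)
  d <- vapply(idx, function(i) sqrt(sum((x[i, ] - query)^2)), numeric(1))
  nn <- idx[order(d)][seq_len(k)]
  sum(label[nn] == 1L) / k
}

# Brute-force threshold minimizer: evaluates every midpoint candidate.
oracle_threshold_errors <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- (u[-length(u)] + u[-1]) / 2
  errs <- vapply(cand, function(t) {
    sum(as.integer(scores > t) != labels)
  }, numeric(1))
  list(cand = cand, errs = errs, min = min(errs))
}

# Direct textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small, fast synthetic cohort for pipeline tests.
small_cohort <- function(seed = 1, n = 60L) {
  generate_cohort(cohort_config(n_normal = n, n_glaucoma = n, seed = seed))
}
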