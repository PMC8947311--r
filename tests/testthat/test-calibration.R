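test_that("derived importance weights are nonnegative and sum to one", {
  ref <- build_reference(small_cohort(seed = 2, n = 80))
  w <- derive_importance(ref, nrounds = 40, seed = 1)
  expect_length(w, 6)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_named(w, igri_features())
})

test_that("a single informative feature takes the largest weight", {
  set.seed(30)
  n <- 300
  x <- matrix(runif(n * 6), ncol = 6,
              dimnames = list(NULL, igri_features()))
  y <- as.integer(x[, "RNFL_I"] > 0.5)     # label determined by RNFL_I alone
  cohort <- as.data.frame(x)
  cohort$label <- y
  w <- derive_importance(cohort, nrounds = 40, seed = 3)
  expect_identical(names(which.max(w)), "RNFL_I")
  expect_gt(w[["RNFL_I"]], 0.5)
})

test_that("labels independent of features never dominate one weight", {
  # permutation-null sanity bound: no weight above 0.5 across 20 seeds
  set.seed(31)
  n <- 120
  x <- matrix(runif(n * 6), ncol = 6,
              dimnames = list(NULL, igri_features()))
  cohort <- as.data.frame(x)
  maxw <- vapply(1:20, function(s) {
    set.seed(400 + s)
    cohort$label <- sample(rep(0:1, n / 2))
    w <- derive_importance(cohort, nrounds = 30, seed = s)
    max(w)
  }, numeric(1))
  expect_true(all(maxw < 0.5))
})

test_that("importance is invariant to row shuffling at fixed seed", {
  coh <- small_cohort(seed = 6, n = 100)
  ref <- build_reference(coh)
  w1 <- derive_importance(ref, nrounds = 30, seed = 5)
  set.seed(99)
  p <- sample(nrow(ref$x))
  refp <- reference_dataset(ref$x[p, ], ref$label[p],
                            provenance = "synthetic")
  w2 <- derive_importance(refp, nrounds = 30, seed = 5)
  expect_identical(as.numeric(w1), as.numeric(w2))
})

test_that("constant features get zero importance with a warning", {
  coh <- small_cohort(seed = 7, n = 80)
  ref <- build_reference(coh)
  x <- ref$x
  x[, "IOP"] <- 0.5
  refc <- reference_dataset(x, ref$label, provenance = "synthetic")
  expect_warning(w <- derive_importance(refc, nrounds = 30, seed = 1),
                 "constant")
  expect_identical(w[["IOP"]], 0)
})

test_that("threshold derivation matches the published examples exactly", {
  t1 <- derive_threshold(c(0.1, 0.2, 0.8, 0.9), c(0L, 0L, 1L, 1L))
  expect_equal(as.numeric(t1), 0.5)
  expect_identical(attr(t1, "misclassified"), 0)

  t2 <- derive_threshold(c(0.1, 0.6, 0.2, 0.9), c(0L, 1L, 0L, 1L))
  expect_gt(as.numeric(t2), 0.2)
  expect_lt(as.numeric(t2), 0.6)
  expect_identical(attr(t2, "misclassified"), 0)

  expect_error(derive_threshold(rep(0.4, 5), c(0L, 1L, 0L, 1L, 0L)),
               "identical")
  expect_error(derive_threshold(runif(5), rep(1L, 5)), "both classes")
})

test_that("threshold equals the exhaustive brute-force minimizer", {
  for (i in 1:20) {
    set.seed(500 + i)
    n <- sample(c(20, 100, 200, 500), 1)
    labels <- sample(0:1, n, replace = TRUE)
    # overlapping classes, some with duplicated score values
    scores <- round(rnorm(n, mean = 0.3 + 0.25 * labels, sd = 0.15), 2)
    scores <- pmin(pmax(scores, 0), 1)
    if (length(unique(scores)) < 2 || length(unique(labels)) < 2) next
    thr <- derive_threshold(scores, labels)
    oracle <- oracle_threshold_errors(scores, labels)
    expect_identical(as.numeric(attr(thr, "misclassified")), oracle$min)
    # the returned cut achieves the oracle minimum when applied directly
    expect_identical(sum(as.integer(scores > as.numeric(thr)) != labels),
                     as.integer(oracle$min))
  }
})

test_that("ratio sweep reports per-ratio misclassification and the argmin", {
  coh <- small_cohort(seed = 12, n = 120)
  ref <- build_reference(coh)
  sw <- suppressWarnings(
    sweep_ratio(coh, ref, candidate_ratios = c(1, 0.8),
                leave_one_out = TRUE))
  expect_identical(nrow(sw), 2L)
  expect_true(all(sw$misclassification >= 0 & sw$misclassification <= 1))
  expect_identical(attr(sw, "best"), which.min(sw$misclassification))
  # base-only (1.0) misclassification should not beat adding an informative
  # NNI on a clustered cohort
  expect_lte(sw$misclassification[sw$base_ratio == 0.8],
             sw$misclassification[sw$base_ratio == 1])
  # a single candidate equals a direct evaluation
  sw1 <- suppressWarnings(
    sweep_ratio(coh, ref, candidate_ratios = 0.8, leave_one_out = TRUE))
  expect_identical(sw1$misclassification,
                   sw$misclassification[sw$base_ratio == 0.8])
  expect_error(sweep_ratio(coh, ref, candidate_ratios = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("planted-profile cohorts put RNFL_I and PSD in the top ranks", {
  hits <- vapply(1:20, function(s) {
    coh <- generate_cohort(planted_cohort_config(n_per_class = 150L,
                                                 seed = 700 + s))
    ref <- build_reference(coh)
    w <- derive_importance(ref, nrounds = 40, seed = s)
    top3 <- names(sort(w, decreasing = TRUE))[1:3]
    all(c("RNFL_I", "PSD") %in% top3)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
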