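test_that("misclassification rate matches hand counts and a loop oracle", {
  expect_identical(misclassification_rate(c(0.679, 0.191), c(1L, 0L), 0.36), 0)
  expect_identical(misclassification_rate(c(0.679, 0.191), c(0L, 1L), 0.36), 1)
  expect_error(misclassification_rate(numeric(0), integer(0)), "empty")

  set.seed(40)
  scores <- runif(50)
  labels <- sample(0:1, 50, replace = TRUE)
  loop <- 0
  for (i in 1:50) {
    pred <- if (scores[i] > 0.36) 1L else 0L
    if (pred != labels[i]) loop <- loop + 1
  }
  expect_identical(misclassification_rate(scores, labels, 0.36), loop / 50)
  # permutation invariance
  p <- sample(50)
  expect_identical(misclassification_rate(scores[p], labels[p], 0.36),
                   loop / 50)
})

test_that("group summary reports means, sds and Welch tests", {
  gs <- group_summary(c(rep(0.2, 5), rep(0.6, 4)),
                      rep(c("normal", "glaucoma"), c(5, 4)))
  expect_equal(gs$summary$mean[gs$summary$group == "normal"], 0.2)
  expect_equal(gs$summary$mean[gs$summary$group == "glaucoma"], 0.6)
  expect_identical(gs$summary$n, c(4L, 5L))
  expect_error(group_summary(1:4, rep("a", 4), pairs = list(c("a", "b"))),
               "unknown group")

  # seeded Gaussian groups: means within 3 SE of the generative truth
  set.seed(41)
  a <- rnorm(200, 0.3, 0.05); b <- rnorm(200, 0.7, 0.05)
  gs2 <- group_summary(c(a, b), rep(c("n", "g"), each = 200),
                       pairs = list(c("g", "n")))
  se <- 0.05 / sqrt(200)
  expect_lt(abs(gs2$summary$mean[gs2$summary$group == "n"] - 0.3), 3 * se)
  expect_lt(abs(gs2$summary$mean[gs2$summary$group == "g"] - 0.7), 3 * se)
  expect_lt(gs2$tests$p_value, 1e-10)

  # identical groups: null p-values are large on average
  ps <- vapply(1:10, function(s) {
    set.seed(50 + s)
    x <- rnorm(60, 0.5, 0.1)
    group_summary(x, rep(c("a", "b"), 30),
                  pairs = list(c("a", "b")))$tests$p_value
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.8)
})

test_that("overlap coefficient behaves at the extremes", {
  s <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  l <- rep(c(0L, 1L), each = 50)
  expect_identical(overlap_coefficient(s, l), 0)       # disjoint support
  # both classes seeing the very same values -> identical histograms
  expect_equal(overlap_coefficient(c(s, s), rep(c(0L, 1L), each = 100)), 1)
  expect_error(overlap_coefficient(s, rep(1L, 100)), "both classes")
})

test_that("NNI ablation is an exact no-op at nni_ratio 0 and helps a perfect NNI", {
  coh <- small_cohort(seed = 20, n = 80)
  ref <- build_reference(coh)
  m0 <- index_model(base_ratio = 1, nni_ratio = 0)
  ab0 <- suppressWarnings(
    ablation_nni(coh, ref, model = m0, leave_one_out = TRUE))
  expect_equal(ab0["with_nni", -1], ab0["base_only", -1],
               ignore_attr = TRUE)
  expect_identical(ab0["with_nni", "overlap"] - ab0["base_only", "overlap"], 0)

  # a cohort where the NNI equals the true label cannot do worse: classes
  # separate cleanly only in IOP (weight 0.07), so the base index overlaps
  # heavily while the k nearest neighbors are always same-class
  set.seed(25)
  n2 <- 100
  mk <- function(iop_mean) data.frame(
    PSD = runif(n2, 2, 14), MD = runif(n2, -20, 4),
    RNFL_S = runif(n2, 30, 150), RNFL_I = runif(n2, 30, 170),
    RNFL_T = runif(n2, 30, 100), IOP = rnorm(n2, iop_mean, 0.4))
  coh2 <- rbind(mk(8), mk(26))
  coh2$label <- rep(c(0L, 1L), each = n2)
  ref2 <- build_reference(coh2)
  ab <- suppressWarnings(ablation_nni(coh2, ref2, leave_one_out = TRUE))
  expect_lte(ab["with_nni", "misclassification"],
             ab["base_only", "misclassification"])
  expect_lt(ab["with_nni", "overlap"], ab["base_only", "overlap"])
})

test_that("MD correlation matches the textbook formula and null behaves", {
  coh <- small_cohort(seed = 21, n = 100)
  ref <- build_reference(coh)
  sc <- suppressWarnings(
    score_records(coh, reference = ref, leave_one_out = TRUE))
  mc <- md_correlation(coh, sc$igri)
  g <- coh$label == 1L
  expect_equal(mc$r, oracle_pearson(coh$MD[g], sc$igri[g]),
               tolerance = 1e-12)
  expect_identical(mc$abs_r, abs(mc$r))
  expect_identical(mc$n, sum(g))

  # scores exactly affine-decreasing in MD -> |r| = 1
  md <- coh$MD[g]
  aff <- md_correlation(coh[g, c(igri_features())], 0.9 - 0.01 * md)
  expect_equal(aff$abs_r, 1, tolerance = 1e-12)

  # scores independent of MD stay weakly correlated
  rs <- vapply(1:10, function(s) {
    set.seed(60 + s)
    md_correlation(coh[g, igri_features()], runif(sum(g)))$abs_r
  }, numeric(1))
  expect_true(all(rs < 0.3))

  expect_error(md_correlation(coh[g, igri_features()], rep(0.4, sum(g))),
               "constant")
})

test_that("evaluate_cohort bundles a coherent report", {
  coh <- small_cohort(seed = 22, n = 100)
  ref <- build_reference(coh)
  rep <- suppressWarnings(evaluate_cohort(coh, ref, leave_one_out = TRUE))
  expect_identical(rep$n, 200L)
  expect_true(rep$in_sample)
  expect_true(rep$misclassification >= 0 && rep$misclassification <= 1)
  expect_setequal(rep$groups$group, c("glaucoma", "normal"))
  expect_gt(rep$groups$mean[rep$groups$group == "glaucoma"],
            rep$groups$mean[rep$groups$group == "normal"])
  expect_lt(rep$welch$p_value, 0.01)
  expect_identical(rownames(rep$ablation), c("with_nni", "base_only"))
  expect_true(all(c("normal", "early") %in% rep$stage_means$group))
})
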