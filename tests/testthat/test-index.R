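test_that("base index reproduces the published worked example", {
  printed <- c(0.5386, 0.4667, 0.6889, 0.7231, 0.6889, 0.25)
  expect_equal(round(compute_base(printed), 4), 0.5971)
  expect_identical(compute_base(rep(1, 6)), 1)
  expect_identical(compute_base(rep(0, 6)), 0)
  expect_error(compute_base(printed, published_weights() * 0.9), "sum to 1")
})

test_that("final index is the published convex combination", {
  expect_equal(round(compute_igri(0.5971, 1.0), 3), 0.678)
  for (x in c(0, 0.25, 0.7, 1)) {
    expect_equal(compute_igri(x, x), x)   # convex-combination identity
  }
  expect_identical(compute_igri(0, 0), 0)
})

test_that("full pipeline reproduces the published glaucoma row at 0.679", {
  # reference engineered so the worked example's 5 nearest rows are glaucoma
  set.seed(4)
  xq <- transform_records(worked_example_record())
  near <- matrix(rep(xq, each = 5), 5) + matrix(runif(30, -0.01, 0.01), 5)
  far <- matrix(runif(36, 0, 0.05), 6, 6)
  ref <- reference_dataset(rbind(pmin(pmax(near, 0), 1), far),
                           c(rep(1L, 5), rep(0L, 6)))
  s <- score_records(worked_example_record(), reference = ref)
  expect_identical(s$nni, 1)
  expect_equal(round(s$base, 4), 0.5982)    # exact arithmetic, RNFL_S 0.6988
  expect_equal(round_half_up(s$igri, 3), 0.679)
  expect_identical(s$predicted_class, 1L)
  expect_identical(as.character(s$stage), "intermediate")
})

test_that("pipeline extremes hit 0 and 1", {
  severe <- exam_records(16.9, -24.1, 6, 0, 20, 29)
  benign <- exam_records(1.2, 6, 170, 190, 108, 5.5)
  set.seed(8)
  # one opposite-class row pinned far away so the k nearest are single-class
  # (the reference container itself requires both classes to be present)
  ref_g <- reference_dataset(rbind(matrix(runif(54, 0.4, 1), 9, 6),
                                   rep(0.01, 6)),
                             c(rep(1L, 9), 0L))
  ref_n <- reference_dataset(rbind(matrix(runif(54, 0, 0.6), 9, 6),
                                   rep(0.99, 6)),
                             c(rep(0L, 9), 1L))
  # severe extreme with an (almost) all-glaucoma reference
  s1 <- score_records(severe, reference = ref_g)
  expect_identical(s1$igri, 1)
  # benign extreme against an (almost) all-normal reference
  s0 <- suppressWarnings(score_records(benign, reference = ref_n))
  expect_lt(s0$igri, 0.05)
  expect_identical(s0$predicted_class, 0L)
})

test_that("classification is strict at the threshold", {
  expect_identical(classify_igri(c(0.679, 0.191, 0.369, 0.36)),
                   c(1L, 0L, 1L, 0L))
})

test_that("MD staging partitions the line with the documented boundaries", {
  md <- c(-13, -12.001, -12, -8, -5, -4.999, -2, 0, 5)
  st <- as.character(stage_by_md(md))
  expect_identical(st, c("advanced", "advanced", "intermediate",
                         "intermediate", "intermediate", "early", "early",
                         "early", "early"))
  # every finite MD gets exactly one stage (no gaps, no overlaps)
  set.seed(9)
  grid <- runif(500, -40, 10)
  expect_false(anyNA(stage_by_md(grid)))
  # normal-classified cases stage as normal regardless of MD
  expect_identical(as.character(stage_by_md(c(-20, -8), c(0L, 0L))),
                   c("normal", "normal"))
})

test_that("index is in [0,1] and monotone in severity for random records", {
  set.seed(21)
  n <- 1000
  recs <- data.frame(
    PSD = runif(n, 0, 25), MD = runif(n, -35, 8),
    RNFL_S = runif(n, 0, 250), RNFL_I = runif(n, 0, 250),
    RNFL_T = runif(n, 0, 250), IOP = runif(n, 2, 60))
  xn <- transform_records(recs)
  base <- compute_base(xn)
  nni <- sample(0:5, n, replace = TRUE) / 5
  igri <- compute_igri(base, nni)
  expect_true(all(igri >= 0 & igri <= 1))

  # worsen severity-aligned coordinates, NNI held fixed -> index never drops
  worse <- recs
  worse$PSD <- worse$PSD + 2
  worse$MD <- worse$MD - 3
  worse$RNFL_I <- pmax(worse$RNFL_I - 20, 0)
  igri2 <- compute_igri(compute_base(transform_records(worse)), nni)
  expect_true(all(igri2 >= igri - 1e-12))
})
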