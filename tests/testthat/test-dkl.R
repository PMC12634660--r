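test_that("dkl reproduces the hand-computed two-bin value", {
  # D_KL((1/2,1/2) || (1/4,3/4)) = 0.5 log 2 + 0.5 log(2/3)
  expect_equal(dkl(c(0.5, 0.5), c(0.25, 0.75), pseudocount = 0),
               0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(dkl(c(0.5, 0.5), c(0.25, 0.75), pseudocount = 0),
               0.1438410362, tolerance = 1e-9)
})

test_that("dkl is zero iff the distributions coincide, else positive", {
  withr::local_seed(19)
  for (i in 1:200) {
    p <- rexp(8); p <- p / sum(p)
    q <- rexp(8); q <- q / sum(q)
    expect_equal(dkl(p, p, pseudocount = 0), 0)
    expect_gt(dkl(p, q, pseudocount = 0), 0)
  }
  expect_error(dkl(c(0.5, 0.5), c(0.5, 0.25, 0.25)), "equal length")
  expect_error(dkl(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
})

test_that("dkl equals direct summation over the support", {
  withr::local_seed(29)
  for (i in 1:50) {
    p <- rexp(32); p[sample(32, 5)] <- 0; p <- p / sum(p)
    q <- rexp(32); q <- q / sum(q)
    eps <- 1e-6
    qq <- (q + eps) / sum(q + eps)
    direct <- sum(ifelse(p > 0, p * log(p / qq), 0))
    expect_equal(dkl(p, q, pseudocount = eps), direct, tolerance = 1e-12)
  }
})

test_that("label_distribution pools non-missing frames", {
  s <- seq_fixture(list(c(0L, 0L, 1L, -1L), c(1L, 1L, -1L, -1L)))
  d <- label_distribution(s, 3L)
  expect_equal(d, c(2, 3, 0) / 5)
})

test_that("bout-shuffle control preserves bout durations and composition", {
  withr::local_seed(37)
  labels <- sample(0:5, 800, replace = TRUE)
  s <- seq_fixture(list(labels), context = "dyadic")
  sh <- shuffle_control(s[1, ], seed = 3L)
  expect_equal(nrow(sh), 1L)
  orig <- soseq:::rle_intervals(labels)
  new <- soseq:::rle_intervals(sh$labels[[1]])
  expect_equal(length(sh$labels[[1]]), length(labels))
  expect_equal(tabulate(sh$labels[[1]] + 1L, 6L), tabulate(labels + 1L, 6L))
  # permuted bouts can merge when same-syllable bouts become adjacent, so the
  # bout count can only shrink
  expect_lte(nrow(new), nrow(orig))
  expect_false(identical(sh$labels[[1]], labels))
})

test_that("aligned divergence time-course has sane structure on synthetic data", {
  exp <- simulate_experiment(tiny_config(seed = 16L))
  dseq <- exp$sequences[exp$sequences$context == "dyadic", ]
  ann <- pool_annotations(exp$annotations)
  tc <- aligned_timecourse(dseq, ann, 32L, "active", n_boot = 200L, seed = 2L)
  expect_s3_class(tc, "soseq_dkl_timecourse")
  co <- tidy(tc)
  expect_true(all(co$dkl >= 0, na.rm = TRUE))
  expect_true(all(co$p_raw > 0 & co$p_raw <= 1, na.rm = TRUE))
  expect_true(all(diff(co$offset_lo) > 0))
  expect_equal(min(co$offset_lo), -125)
  # untested bins are masked, not significant
  expect_true(all(!co$significant[is.na(co$p_raw)]))
  # determinism in the seed
  tc2 <- aligned_timecourse(dseq, ann, 32L, "active", n_boot = 200L, seed = 2L)
  expect_equal(tidy(tc2), co)
})

test_that("joint (pair-symmetrised) time-course runs and stays non-negative", {
  exp <- simulate_experiment(tiny_config(seed = 18L))
  dseq <- exp$sequences[exp$sequences$context == "dyadic", ]
  ann <- pool_annotations(exp$annotations)
  tc <- joint_timecourse(dseq, ann, 32L, "active", n_boot = 200L, seed = 2L)
  co <- tidy(tc)
  expect_true(all(co$dkl >= 0, na.rm = TRUE))
  expect_gt(sum(!is.na(co$p_raw)), 10L)
})
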