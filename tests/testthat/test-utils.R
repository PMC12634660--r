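test_that("vectorised Mann-Whitney matches wilcox.test with ties", {
  withr::local_seed(11)
  X <- cbind(rnorm(14), sample(1:4, 14, replace = TRUE),
             c(rep(0, 7), rep(1, 7)) + rnorm(14, sd = 0.4))
  grp <- rep(c(TRUE, FALSE), each = 7L)
  res <- soseq:::mwu_test_cols(X, grp)
  for (j in 1:3) {
    w <- suppressWarnings(wilcox.test(X[grp, j], X[!grp, j],
                                      exact = FALSE, correct = TRUE))
    expect_equal(res$statistic[j], unname(w$statistic))
    expect_equal(res$p_value[j], w$p.value, tolerance = 1e-12)
  }
  oneside <- soseq:::mwu_test_cols(X, grp, alternative = "greater")
  w1 <- suppressWarnings(wilcox.test(X[grp, 3], X[!grp, 3], exact = FALSE,
                                     correct = TRUE, alternative = "greater"))
  expect_equal(oneside$p_value[3], w1$p.value, tolerance = 1e-12)
})

test_that("p-value adjustment wraps p.adjust", {
  p <- c(0.001, 0.02, 0.04, 0.2, 0.9)
  expect_equal(soseq:::adjust_p(p, "benjamini_hochberg"),
               p.adjust(p, "BH"))
  expect_equal(soseq:::adjust_p(p, "bonferroni"), p.adjust(p, "bonferroni"))
  expect_equal(soseq:::adjust_p(p, "none"), p)
})

test_that("derived seeds are deterministic, distinct, and leave the RNG alone", {
  s1 <- soseq:::derive_seeds(123L, c("a", "b", "c"))
  s2 <- soseq:::derive_seeds(123L, c("a", "b", "c"))
  expect_identical(s1, s2)
  expect_length(unique(s1), 3L)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  set.seed(99)
  before <- .Random.seed
  invisible(soseq:::derive_seeds(5L, letters))
  expect_identical(.Random.seed, before)
})

test_that("with_seed restores RNG state and reproduces draws", {
  a <- soseq:::with_seed(77L, runif(5))
  b <- soseq:::with_seed(77L, runif(5))
  expect_identical(a, b)
  set.seed(1)
  x1 <- runif(3)
  set.seed(1)
  invisible(soseq:::with_seed(77L, runif(10)))
  expect_identical(runif(3), x1)
})

test_that("rle_intervals produces half-open 0-based runs", {
  iv <- soseq:::rle_intervals(c(4L, 4L, -1L, 2L, 2L, 2L, 4L))
  expect_equal(iv$syllable, c(4L, -1L, 2L, 4L))
  expect_equal(iv$start, c(0L, 2L, 3L, 6L))
  expect_equal(iv$end, c(2L, 3L, 6L, 7L))
})
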