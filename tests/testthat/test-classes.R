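test_that("kinematic classification matches the worked examples", {
  cls <- classify_kinematics(c(50, 250, 50, 250), c(10, -200, 200, 100))
  expect_equal(cls$class, c("contact", "approach", "leave", "far_stationary"))
})

test_that("the four classes partition the admissible plane", {
  withr::local_seed(41)
  x <- runif(2000, 0, 500)
  y <- runif(2000, -400, 400)
  keep <- x + y >= 0            # end distance cannot be negative
  cls <- classify_kinematics(x[keep], y[keep])
  expect_true(all(cls$class %in%
                    c("contact", "approach", "leave", "far_stationary")))
  expect_equal(sum(is.na(cls$class)), 0L)
  # class regions are consistent with the boundary definitions
  s <- x[keep] + y[keep]
  expect_true(all((cls$class == "approach") ==
                    (x[keep] > 100 & s < 100)))
  expect_true(all((cls$class == "leave") == (x[keep] < 100 & s > 100)))
  expect_error(classify_kinematics(-5, 10), "non-negative")
})

test_that("syntax kinematics read distances at window start and end", {
  sy <- tibble::tibble(recording_id = "d1", s1 = 0L, s2 = 1L, s3 = 2L,
                       start = c(0L, 5L), end = c(5L, 10L))
  imd <- list(d1 = seq(100, 190, by = 10))
  sk <- syntax_kinematics(sy, imd)
  expect_equal(sk$x, c(100, 150))
  expect_equal(sk$y, c(40, 40))
})

test_that("class/family association matches a direct chi-square test", {
  withr::local_seed(43)
  classes <- sample(c("approach", "leave"), 300, replace = TRUE,
                    prob = c(0.5, 0.5))
  member <- ifelse(classes == "approach",
                   runif(300) < 0.7, runif(300) < 0.2)
  ca <- class_family_association(classes, list(fam = member))
  tab <- table(factor(member, levels = c(FALSE, TRUE)), classes)
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(ca$tests$statistic, unname(oracle$statistic))
  expect_equal(ca$tests$p_raw, oracle$p.value)
  expect_true(ca$tests$significant)
})

test_that("class divergence matrix is zero-diagonal non-negative", {
  withr::local_seed(47)
  sy <- tibble::tibble(
    class = sample(c("a", "b", "c"), 200, replace = TRUE),
    s1 = sample(0:7, 200, replace = TRUE),
    s2 = sample(0:7, 200, replace = TRUE),
    s3 = sample(0:7, 200, replace = TRUE))
  D <- class_dkl_matrix(sy, 8L)
  expect_equal(diag(D), setNames(rep(0, 3), c("a", "b", "c")))
  expect_true(all(D >= 0))
  expect_false(isTRUE(all.equal(D, t(D))))  # D_KL is asymmetric
})

test_that("random-pair distance control approaches the uniform-square mean", {
  # E|X-Y| for two uniform points on a 453 mm square = 0.5214... * 453
  withr::local_seed(53)
  n <- 5000L
  tr <- dplyr::bind_rows(
    centroid_track("d1", "a1", runif(n, 0, 453), runif(n, 0, 453)),
    centroid_track("d1", "a2", runif(n, 0, 453), runif(n, 0, 453)))
  ic <- imd_controls(tr, seed = 2L, n_pairs = 2e5)
  expect_equal(ic$mean_random, 0.52140543 * 453, tolerance = 0.01)
  # for independent uniform tracks, shuffling should not change the mean much
  expect_equal(ic$mean_observed, ic$mean_shuffled, tolerance = 0.05)
  dens_sum <- tapply(ic$histogram$density, ic$histogram$series,
                     function(d) sum(d) * 10)
  expect_equal(as.numeric(dens_sum), rep(1, 3), tolerance = 1e-6)
})

test_that("position density integrates to one and scores corner occupancy", {
  withr::local_seed(59)
  n <- 4000L
  tr <- centroid_track("r", "a", runif(n, 0, 453), runif(n, 0, 453))
  kde <- position_kde(tr)
  z <- kde$kde$z
  dx <- diff(kde$kde$x[1:2]); dy <- diff(kde$kde$y[1:2])
  expect_equal(sum(z) * dx * dy, 1, tolerance = 0.1)
  # uniform positions: corner fraction ~ 4 * quarter-circle area / arena area
  expect_lt(abs(kde$corner_fraction - pi * 100^2 / 453^2), 0.02)
  expect_error(position_kde(centroid_track("r", "a", runif(50, 0, 453),
                                           runif(50, 0, 453))),
               "100 positions")
})
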