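test_that("bout extraction handles runs, missing frames, and bout breaks", {
  s <- seq_fixture(list(c(0L, 0L, 1L, 1L, 1L, -1L, 1L, 2L)))
  b <- extract_bouts(s)
  expect_equal(b$syllable, c(0L, 1L, 1L, 2L))
  expect_equal(b$start, c(0L, 2L, 6L, 7L))
  expect_equal(b$end, c(2L, 5L, 7L, 8L))
  expect_equal(b$duration, c(2L, 3L, 1L, 1L))
})

test_that("bout extraction matches a brute-force frame scan", {
  withr::local_seed(21)
  labels <- sample(c(-1L, 0L:5L), 5000, replace = TRUE,
                   prob = c(0.1, rep(0.15, 6)))
  b <- extract_bouts(seq_fixture(list(labels)))
  # naive scan
  naive <- list()
  cur <- -2L; start <- 0L
  for (f in seq_along(labels)) {
    if (labels[f] != cur) {
      if (cur >= 0L) naive[[length(naive) + 1L]] <- c(cur, start, f - 1L)
      cur <- labels[f]; start <- f - 1L
    }
  }
  if (cur >= 0L) naive[[length(naive) + 1L]] <- c(cur, start, length(labels))
  nv <- do.call(rbind, naive)
  expect_equal(b$syllable, nv[, 1])
  expect_equal(b$start, nv[, 2])
  expect_equal(b$end, nv[, 3])
})

test_that("onset and frame proportions are normalized and correct", {
  s <- seq_fixture(list(c(0L, 0L, 0L, 1L)))
  p <- syllable_proportions(extract_bouts(s), 2L)
  expect_equal(p$onset_prop, c(0.5, 0.5))
  expect_equal(p$frame_prop, c(0.75, 0.25))

  s2 <- seq_fixture(list(c(0L, 1L, 0L)))
  p2 <- syllable_proportions(extract_bouts(s2), 3L)
  expect_equal(p2$onset_prop[p2$syllable == 0L], 2 / 3)
  expect_equal(p2$onset_prop[p2$syllable == 2L], 0)
  expect_equal(sum(p2$onset_prop), 1)
  expect_equal(sum(p2$frame_prop), 1)
})

test_that("syllable retention uses a strict 0.5% pooled-onset threshold", {
  props <- tibble::tibble(syllable = 0:3,
                          n_bouts = c(700L, 200L, 96L, 4L))
  kept <- filter_syllables(props)
  expect_equal(kept$syllable, c(0L, 1L, 2L))
  expect_equal(kept$new_id, 0:2)
  expect_equal(kept$pooled_onset_prop, c(0.7, 0.2, 0.096))

  boundary <- tibble::tibble(syllable = 0:1, n_bouts = c(995L, 5L))
  expect_equal(filter_syllables(boundary)$syllable, 0L)  # exactly 0.005: dropped
  expect_equal(nrow(filter_syllables(boundary, threshold = 0)), 2L)
})

test_that("distance moved sums Euclidean steps and skips missing frames", {
  tr <- centroid_track("r", "a", c(0, 3, 3), c(0, 4, 4))
  expect_equal(distance_moved(tr)$distance_mm, 5)
  tr2 <- centroid_track("r", "a", c(0, 3, NA, 3), c(0, 4, NA, 4))
  expect_equal(distance_moved(tr2)$distance_mm, 5)  # steps through NA skipped
  tr3 <- centroid_track("r", "a", rep(10, 50), rep(10, 50))
  expect_equal(distance_moved(tr3)$distance_mm, 0)
})

test_that("context comparison flags shifted syllables and skips absent ones", {
  mk <- function(ctx, base) {
    tibble::tibble(
      recording_id = paste0(ctx, 1:4), animal_id = paste0("a", 1:4),
      context = ctx) |>
      tidyr::crossing(syllable = 0:2) |>
      dplyr::mutate(onset_prop = dplyr::case_when(
        syllable == 0 ~ base + 0.01 * as.integer(factor(animal_id)),
        syllable == 1 ~ 1 - (base + 0.01 * as.integer(factor(animal_id))),
        TRUE ~ 0))
  }
  props <- dplyr::bind_rows(mk("solitary", 0.1), mk("dyadic", 0.4))
  expect_warning(mod <- compare_contexts(props), "absent")
  expect_s3_class(mod, "soseq_context_modulation")
  expect_equal(mod$dm, c(0L, 1L))
  expect_equal(mod$skipped, 2L)
  expect_true(2L %in% mod$du)
  expect_equal(nrow(tidy(mod)), 2L)
  expect_error(compare_contexts(props[props$context == "dyadic", ]),
               "2 animals")
})

test_that("contact association reproduces the chi-square oracle", {
  # 40 bouts of syllable 0 alternating with syllable 1; contact covers the
  # first half of the recording, plus a bias: syllable 0 dominates inside
  labels1 <- c(rep(c(0L, 1L), each = 5, times = 100),
               rep(c(0L, 1L, 1L, 1L), each = 5, times = 50))
  labels2 <- c(rep(c(1L, 0L), each = 5, times = 100),
               rep(c(1L, 0L, 0L, 0L), each = 5, times = 50))
  s <- seq_fixture(list(labels1, labels2), context = "dyadic")
  b <- extract_bouts(s)
  n_frames <- length(labels1)
  ann <- tibble::tibble(recording_id = s$recording_id, contact_type = "active",
                        start = 0L, end = 1000L)
  ca <- contact_association(b, ann, n_frames)
  expect_s3_class(ca, "soseq_contact_association")
  # oracle: rebuild the 2x2 table for syllable 0 and compare
  onset_in <- b$start < 1000L
  m <- matrix(c(sum(b$syllable == 0 & onset_in), sum(b$syllable != 0 & onset_in),
                sum(b$syllable == 0 & !onset_in), sum(b$syllable != 0 & !onset_in)),
              2L)
  oracle <- suppressWarnings(chisq.test(m, correct = FALSE))
  row0 <- ca$tests[ca$tests$syllable == 0L, ]
  expect_equal(row0$statistic, unname(oracle$statistic))
  expect_equal(row0$p_raw, oracle$p.value)
  expect_equal(row0$p_adjusted, min(1, oracle$p.value * nrow(ca$tests)))
  expect_true(all(c("factor(syllable)", "in_contact", "factor(syllable):in_contact") %in%
                    ca$anova$term))
})

test_that("inter-mouse distance and quartile assignment are correct", {
  t1 <- centroid_track("d1", "a1", c(0, 0), c(0, 0))
  t2 <- centroid_track("d1", "a2", c(3, 30), c(4, 40))
  imd <- imd_series(dplyr::bind_rows(t1, t2))
  expect_equal(imd, c(5, 50))
  expect_error(imd_series(t1), "two tracks")

  withr::local_seed(3)
  s <- seq_fixture(list(sample(0:3, 2000, replace = TRUE),
                        sample(0:3, 2000, replace = TRUE)),
                   context = "dyadic")
  b <- extract_bouts(s)
  series <- list(seq(0, 400, length.out = 2000),
                 seq(400, 0, length.out = 2000))
  names(series) <- unique(s$recording_id)
  qa <- quartile_association(b, series)
  expect_equal(qa$edges,
               quantile(unlist(series), c(0.25, 0.5, 0.75), names = FALSE))
  sums <- tapply(qa$table$onset_prop, qa$table$quartile, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-12)
})
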