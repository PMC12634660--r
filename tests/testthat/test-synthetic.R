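test_that("generated transition matrices are zero-diagonal row-stochastic", {
  cfg <- tiny_config()
  for (ctx in c("solitary", "dyadic")) {
    mats <- generate_transition_matrices(cfg, ctx, n_animals = 3L)
    for (M in c(list(mats$base), mats$animals)) {
      expect_equal(rowSums(M), rep(1, cfg$n_syllables), tolerance = 1e-12)
      expect_true(all(diag(M) == 0))
      expect_true(all(M >= 0))
    }
  }
})

test_that("DM planting is mass-preserving and leaves other columns untouched", {
  cfg <- tiny_config()
  sol <- generate_transition_matrices(cfg, "solitary", n_animals = 2L)$base
  dya <- generate_transition_matrices(cfg, "dyadic", n_animals = 2L)$base
  planted <- cfg$planted_dm + 1L
  other <- setdiff(seq_len(cfg$n_syllables), planted)
  expect_equal(dya[, other], sol[, other], tolerance = 1e-12)
  expect_equal(rowSums(dya[, planted]), rowSums(sol[, planted]),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(dya[, planted], sol[, planted])))
})

test_that("generate_sequence follows the chain and the duration law", {
  cfg <- synthetic_config(n_animals_per_context = 4L, duration_s = 2000,
                          seed = 42L)
  P <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3L, byrow = TRUE)
  lab <- generate_sequence(P, cfg, seed = 5L)
  expect_length(lab, round(cfg$duration_s * cfg$frame_rate))
  expect_true(all(lab %in% 0:2))
  iv <- soseq:::rle_intervals(lab)
  # the cyclic chain 0 -> 1 -> 2 -> 0 must be followed exactly
  nxt <- (iv$syllable[-nrow(iv)] + 1L) %% 3L
  expect_equal(iv$syllable[-1L], nxt)
  # geometric durations with median = duration_median_frames
  expect_true(abs(median(iv$end - iv$start) - cfg$duration_median_frames) <= 1)
  expect_error(generate_sequence(matrix(0.5, 2, 2), cfg, 1L),
               "zero-diagonal")
})

test_that("simulated experiments are deterministic in the seed", {
  e1 <- simulate_experiment(tiny_config(seed = 9L))
  e2 <- simulate_experiment(tiny_config(seed = 9L))
  expect_identical(e1$sequences$labels, e2$sequences$labels)
  expect_identical(e1$tracks$x, e2$tracks$x)
  expect_identical(e1$annotations, e2$annotations)
  e3 <- simulate_experiment(tiny_config(seed = 10L))
  expect_false(identical(e1$sequences$labels, e3$sequences$labels))
})

test_that("experiment structure matches the configuration", {
  cfg <- tiny_config(seed = 2L)
  exp <- simulate_experiment(cfg)
  n_frames <- round(cfg$duration_s * cfg$frame_rate)
  expect_equal(nrow(exp$sequences), 2L * cfg$n_animals_per_context)
  expect_true(all(lengths(exp$sequences$labels) == n_frames))
  expect_true(all(unlist(exp$sequences$labels) %in% c(-1:(cfg$n_syllables - 1L))))
  expect_equal(sort(unique(exp$sequences$context)), c("dyadic", "solitary"))
  # dyadic recordings hold two animals, solitary recordings one
  dy <- table(exp$tracks$recording_id[grepl("^D", exp$tracks$recording_id)])
  expect_true(all(dy == 2L))
  expect_true(all(exp$annotations$contact_type %in% c("active", "passive")))
  expect_true(all(exp$annotations$end > exp$annotations$start))
})

test_that("ground truth records planting direction and network spillover", {
  cfg <- tiny_config(seed = 4L)
  exp <- simulate_experiment(cfg)
  gt <- exp$ground_truth
  expect_setequal(c(gt$planted_up, gt$planted_down), cfg$planted_dm)
  expect_length(gt$expected_onset_shift, cfg$n_syllables)
  # planted-up ids must have positive expected shift, planted-down negative
  expect_true(all(gt$expected_onset_shift[gt$planted_up + 1L] > 0))
  expect_true(all(gt$expected_onset_shift[gt$planted_down + 1L] < 0))
  expect_true(all(!(gt$spillover_ids %in% cfg$planted_dm)))
  expect_true(all(abs(gt$expected_onset_shift[gt$spillover_ids + 1L]) > 0.05))
})

test_that("null configuration plants nothing", {
  cfg <- null_synthetic_config(n_animals_per_context = 4L, duration_s = 240,
                               seed = 8L)
  sol <- generate_transition_matrices(cfg, "solitary", n_animals = 2L)$base
  dya <- generate_transition_matrices(cfg, "dyadic", n_animals = 2L)$base
  expect_equal(dya, sol, tolerance = 1e-12)
  exp <- simulate_experiment(cfg)
  expect_equal(max(abs(exp$ground_truth$expected_onset_shift)), 0,
               tolerance = 1e-10)
  expect_length(exp$ground_truth$spillover_ids, 0L)
})

test_that("planted ids outside the vocabulary are rejected", {
  expect_error(synthetic_config(n_syllables = 8L), "0..n_syllables-1")
  expect_error(tiny_config(planted_dm = c(1L, 40L)), "0..n_syllables-1")
  expect_error(synthetic_config(n_animals_per_context = 3L), "even")
})

test_that("generated contacts reflect proximity below the contact radius", {
  cfg <- tiny_config()
  n <- 400L
  xA <- rep(0, n); yA <- rep(0, n)
  xB <- c(rep(300, 100), rep(50, 100), rep(300, 200))
  yB <- rep(0, n)
  ann <- generate_contacts(xA, yA, xB, yB, cfg, seed = 1L, "rec")
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$start, 100L)
  expect_equal(ann$end, 200L)
  expect_true(ann$contact_type %in% c("active", "passive"))
})
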