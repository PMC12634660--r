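test_that("syntaxes are sliding bout triples within an animal", {
  s <- seq_fixture(list(c(0L, 1L, 2L, 3L, 4L)))
  sy <- extract_syntaxes(extract_bouts(s))
  expect_equal(nrow(sy), 3L)   # 5 bouts -> 3 windows of length 3
  expect_equal(sy$s1, c(0L, 1L, 2L))
  expect_equal(sy$s2, c(1L, 2L, 3L))
  expect_equal(sy$s3, c(2L, 3L, 4L))
  expect_equal(sy$start, c(0L, 1L, 2L))
  expect_equal(sy$end, c(3L, 4L, 5L))
  # fewer bouts than the window is an error, not silence
  s2 <- seq_fixture(list(c(0L, 1L)))
  expect_error(extract_syntaxes(extract_bouts(s2)), "fewer than 3 bouts")
})

test_that("syntax windows never span animals or recordings", {
  s <- seq_fixture(list(c(0L, 1L, 2L), c(3L, 4L, 5L)))
  sy <- extract_syntaxes(extract_bouts(s))
  expect_equal(nrow(sy), 2L)
  expect_true(all(table(sy$recording_id) == 1L))
  expect_false(any(sy$s1 %in% 0:2 & sy$s3 %in% 3:5))
})

test_that("hamming distance and family membership match the worked examples", {
  expect_equal(hamming(c(9, 0, 5), c(9, 0, 10)), 1)
  expect_equal(hamming(c(9, 0, 5), c(0, 5, 10)), 3)
  expect_equal(hamming(c(9, 0, 5), c(9, 0, 5)), 0)
  expect_error(hamming(c(1, 2), c(1, 2, 3)), "equal length")

  sy <- tibble::tibble(s1 = c(9L, 9L, 0L), s2 = c(0L, 0L, 5L),
                       s3 = c(5L, 10L, 10L))
  mem <- is_family_member(sy, c(9L, 0L, 5L))
  expect_equal(mem, c(TRUE, TRUE, FALSE))
})

test_that("a 32-syllable family has 1 + 3*31 members", {
  # enumerate all triples at Hamming distance <= 1 from the reference
  ref <- c(9L, 0L, 5L)
  grid <- expand.grid(s1 = 0:31, s2 = 0:31, s3 = 0:31)
  mem <- is_family_member(grid, ref)
  expect_equal(sum(mem), 1L + 3L * 31L)
})

test_that("family occupancy marks exactly the frames inside member windows", {
  sy <- tibble::tibble(s1 = c(9L, 1L), s2 = c(0L, 1L), s3 = c(5L, 1L),
                       start = c(2L, 10L), end = c(6L, 14L))
  occ <- family_occupancy(sy, c(9L, 0L, 5L), 20L)
  expect_equal(which(occ), 3:6)   # half-open [2, 6) in 0-based frames
})

test_that("rolling occupancy-distance windows are computed exactly", {
  imd <- c(10, 20, 30, 40, 50)
  occ <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  rr <- rolling_relation(imd, occ, window = 3L)
  expect_equal(nrow(rr$windows), 3L)
  expect_equal(rr$windows$cid, c(20, 20, 20))
  expect_equal(rr$windows$occupancy, c(2 / 3, 1 / 3, 1 / 3))
  expect_error(rolling_relation(imd, occ[1:4]), "equal length")
  expect_error(rolling_relation(imd, occ, window = 10L), "longer")
})

test_that("the contact-aligned syntax z-score recovers a planted syntax", {
  exp <- simulate_experiment(tiny_config(seed = 22L))
  sy <- extract_syntaxes(extract_bouts(exp$sequences))
  sy <- sy[sy$context == "dyadic", ]
  ann <- pool_annotations(exp$annotations)
  tc <- zscore_timecourse(sy, ann, "active", min_onsets = 5L)
  expect_s3_class(tc, "soseq_syntax_timecourse")
  zs <- tidy(tc)
  expect_true(all(zs$frequency >= 0 & zs$frequency <= 1, na.rm = TRUE))
  expect_true(all(range(zs$offset) == c(-125, 249)))
  # both planted syntaxes (contact triple and approach family head) are
  # injected near active contacts; the contact triple must rank in the top 4
  expect_true("7,10,12" %in% utils::head(tc$ranking$syntax, 4L))
})
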