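test_that("cosine distance has the right fixed points and bounds", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_distance(1:3, 1:4), "equal length")
  withr::local_seed(5)
  for (i in 1:100) {
    d <- cosine_distance(rnorm(6), rnorm(6))
    expect_true(d >= 0 && d <= 2)
  }
})

test_that("egocentric alignment maps a straight bout onto the +x axis", {
  # bout moving diagonally: aligned path must end at (total length, 0)
  x <- seq(0, 30, length.out = 10) + 100
  y <- seq(0, 40, length.out = 10) + 100
  tr <- centroid_track("r", "a", x, y)
  b <- tibble::tibble(recording_id = "r", animal_id = "a", context = "solitary",
                      light_cycle = "normal", syllable = 0L,
                      start = 0L, end = 10L, duration = 10L)
  m <- egocentric_mean_trajectory(b, tr, L = 10L)
  expect_equal(m$path[1, ], c(0, 0))
  expect_equal(m$path[10, ], c(50, 0), tolerance = 1e-9)
  expect_equal(m$net_displacement, 50, tolerance = 1e-9)
  expect_equal(m$path_length, 50, tolerance = 1e-9)
  expect_equal(m$net_heading_change, 0)
})

test_that("alignment is invariant to global rotation and translation", {
  withr::local_seed(13)
  steps <- cbind(rnorm(15), rnorm(15))
  xy <- apply(steps, 2, cumsum) * 3 + 200
  b <- tibble::tibble(recording_id = "r", animal_id = "a", context = "solitary",
                      light_cycle = "normal", syllable = 0L,
                      start = 0L, end = 15L, duration = 15L)
  tr1 <- centroid_track("r", "a", xy[, 1], xy[, 2])
  m1 <- egocentric_mean_trajectory(b, tr1, L = 8L)
  th <- 1.1
  rot <- cbind(cos(th) * (xy[, 1] - 200) - sin(th) * (xy[, 2] - 200) + 220,
               sin(th) * (xy[, 1] - 200) + cos(th) * (xy[, 2] - 200) + 180)
  tr2 <- centroid_track("r", "a", rot[, 1], rot[, 2])
  m2 <- egocentric_mean_trajectory(b, tr2, L = 8L)
  expect_equal(m1$path, m2$path, tolerance = 1e-8)
  expect_equal(m1$net_heading_change, m2$net_heading_change, tolerance = 1e-8)
})

test_that("heading change accumulates signed wrapped turns", {
  # counter-clockwise square: three +90 degree turns
  x <- c(0, 1, 1, 0, 0)
  y <- c(0, 0, 1, 1, 0)
  expect_equal(soseq:::heading_change(x, y), 3 * pi / 2)
  expect_equal(soseq:::heading_change(rev(x), rev(y)), -3 * pi / 2)
  expect_equal(soseq:::heading_change(c(0, 1, 2), c(0, 0, 0)), 0)
})

test_that("the similarity dendrogram agrees with hclust on cosine distances", {
  withr::local_seed(31)
  paths <- lapply(1:5, function(i) matrix(rnorm(20), 10L, 2L))
  tra <- tibble::tibble(syllable = 0:4, n_instances = 10L,
                        net_displacement = 1, path_length = 2,
                        net_heading_change = 0, path = paths)
  dd <- similarity_dendrogram(tra)
  expect_equal(unname(diag(dd$dist)), rep(0, 5))
  expect_equal(dd$dist, t(dd$dist))
  V <- t(sapply(paths, as.numeric))
  D <- as.matrix(dist(V))  # placeholder shape; fill with cosine distances
  for (i in 1:5) for (j in 1:5) {
    D[i, j] <- if (i == j) 0 else cosine_distance(V[i, ], V[j, ])
  }
  hc <- hclust(as.dist(D), method = "average")
  expect_equal(dd$hclust$height, hc$height)
  expect_equal(dd$hclust$merge, hc$merge)
  expect_match(dd$newick, "^\\(.*\\);$")
})

test_that("movement contrast tests DM lower displacement, higher turning", {
  tra <- tibble::tibble(
    syllable = 0:9,
    n_instances = 20L,
    net_displacement = c(rep(5, 5), rep(50, 5)) + (0:9) * 0.1,
    path_length = 60,
    net_heading_change = c(rep(2, 5), rep(0.1, 5)) + (0:9) * 0.01,
    path = replicate(10, diag(2), simplify = FALSE))
  mt <- movement_class_test(tra, dm = 0:4)
  expect_equal(nrow(mt), 2L)
  expect_true(all(mt$significant))
  swapped <- movement_class_test(tra, dm = 5:9)
  expect_false(any(swapped$significant))
  expect_error(movement_class_test(tra, dm = 0:9), "non-empty")
})

test_that("syllable trajectories cover observed syllables on synthetic data", {
  exp <- simulate_experiment(tiny_config(seed = 6L))
  b <- extract_bouts(exp$sequences)
  tra <- syllable_trajectories(b[b$context == "solitary", ], exp$tracks,
                               min_instances = 5L)
  expect_gt(nrow(tra), 20L)
  expect_true(all(vapply(tra$path, function(p) all(p[1, ] == 0), logical(1))))
  expect_true(all(tra$net_displacement >= 0))
  expect_true(all(tra$path_length >= tra$net_displacement - 1e-9))
})
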