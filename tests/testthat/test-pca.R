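test_that("feature matrices pivot proportions and syntax counts to wide form", {
  exp <- simulate_experiment(tiny_config(seed = 24L))
  props <- syllable_proportions(extract_bouts(exp$sequences), 32L)
  fm <- syllable_feature_matrix(props)
  expect_equal(nrow(fm), 2L * 4L)
  expect_equal(sum(grepl("^syl_", names(fm))), 32L)
  expect_equal(unname(rowSums(as.matrix(fm[, grepl("^syl_", names(fm))]))),
               rep(1, nrow(fm)), tolerance = 1e-12)

  sy <- extract_syntaxes(extract_bouts(exp$sequences))
  sm <- syntax_feature_matrix(sy, min_occurrences = 10L)
  expect_true(all(c("recording_id", "animal_id", "context") %in% names(sm)))
  expect_error(syntax_feature_matrix(sy, min_occurrences = 1e6), "floor")
})

test_that("pca_features matches prcomp up to the sign convention", {
  withr::local_seed(61)
  X <- matrix(rnorm(120), 20L, 6L)
  colnames(X) <- paste0("f", 1:6)
  feats <- dplyr::bind_cols(
    tibble::tibble(recording_id = paste0("r", 1:20),
                   animal_id = paste0("a", 1:20),
                   context = rep(c("solitary", "dyadic"), 10)),
    tibble::as_tibble(X))
  p <- pca_features(feats)
  ref <- prcomp(X, center = TRUE)
  expect_equal(abs(p$loadings), abs(ref$rotation),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(p$var_explained, ref$sdev^2 / sum(ref$sdev^2))
  expect_equal(sum(p$var_explained), 1)
  # sign convention: the largest-magnitude loading of each column is positive
  for (j in seq_len(ncol(p$loadings))) {
    v <- p$loadings[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
  # loadings must agree with the eigendecomposition of the covariance
  ev <- eigen(cov(X))
  for (j in 1:6) {
    expect_equal(abs(sum(p$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  # scores reconstruct the centered data
  S <- as.matrix(p$scores[, paste0("PC", 1:6)])
  expect_equal(S %*% t(p$loadings), scale(X, scale = FALSE),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("is_dm_syntax requires at least two DM syllables in the triple", {
  feats <- c("7,10,12", "7,1,2", "7,10,3", "1,2,3")
  expect_equal(is_dm_syntax(feats, dm = c(7L, 10L, 12L)),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("loading contrast flags DM-dominated components", {
  withr::local_seed(67)
  L <- rbind(matrix(runif(40, 0.5, 1), 8L),   # DM features: large loadings
             matrix(runif(40, 0, 0.05), 8L))  # DU features: tiny loadings
  fake <- structure(list(loadings = L, var_explained = rep(0.2, 5)),
                    class = "soseq_pca")
  lc <- loading_contrast(fake, dm_features = rep(c(TRUE, FALSE), each = 8L))
  expect_equal(nrow(lc), 5L)
  expect_true(all(lc$significant))
  expect_error(loading_contrast(fake, rep(TRUE, 16L)), "non-empty")
})

test_that("silhouette separation is high for separated groups, low for noise", {
  withr::local_seed(71)
  scores <- tibble::tibble(
    recording_id = paste0("r", 1:20), animal_id = paste0("a", 1:20),
    context = rep(c("solitary", "dyadic"), each = 10),
    light_cycle = sample(c("normal", "reversed"), 20, replace = TRUE),
    PC1 = c(rnorm(10, -5, 0.3), rnorm(10, 5, 0.3)),
    PC2 = rnorm(20, 0, 0.3))
  fake <- structure(list(scores = scores), class = "soseq_pca")
  sep <- context_separation(fake)
  expect_gt(sep$silhouette[sep$grouping == "context"], 0.8)
  expect_lt(sep$silhouette[sep$grouping == "light_cycle"], 0.3)
  expect_error(context_separation(fake, "no_such_column"), "not found")
})
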