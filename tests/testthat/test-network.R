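test_that("transition counts and probabilities follow consecutive bouts", {
  s <- seq_fixture(list(c(0L, 0L, 1L, 2L, 2L, 0L, 1L)))
  net <- transition_matrix(extract_bouts(s), 3L)
  expect_s3_class(net, "soseq_transition_network")
  counts <- matrix(0, 3, 3)
  counts[1, 2] <- 2; counts[2, 3] <- 1; counts[3, 1] <- 1
  expect_equal(net$counts, counts)
  expect_equal(net$P[1, ], c(0, 1, 0))
  expect_equal(rowSums(net$P), rep(1, 3))
  expect_length(net$empty_rows, 0L)
})

test_that("rows of estimated transition matrices sum to one when occupied", {
  exp <- simulate_experiment(tiny_config(seed = 12L))
  nets <- transition_networks(extract_bouts(exp$sequences), 32L)
  for (nw in nets$network[1:4]) {
    occupied <- rowSums(nw$counts) > 0
    expect_equal(rowSums(nw$P[occupied, , drop = FALSE]),
                 rep(1, sum(occupied)), tolerance = 1e-12)
    expect_true(all(nw$P >= 0))
  }
})

test_that("eigenvector centrality reproduces the worked 3-node example", {
  P <- matrix(c(0, 0.5, 0.5,
                0, 0, 1,
                1, 0, 0), 3L, byrow = TRUE)
  ec <- eigenvector_centrality(P)
  expect_equal(ec$centrality, c(0.4, 0.2, 0.4), tolerance = 1e-9)
  # invariance: c P = c for the left eigenvector
  expect_equal(as.numeric(ec$centrality %*% P), ec$centrality,
               tolerance = 1e-9)
  expect_equal(sum(ec$centrality), 1)
})

test_that("power iteration matches dense eigendecomposition", {
  withr::local_seed(17)
  for (i in 1:5) {
    M <- matrix(rexp(64), 8L); diag(M) <- 0
    P <- M / rowSums(M)
    ec <- eigenvector_centrality(P)
    ev <- eigen(t(P))
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
    v <- v / sum(v)
    expect_lt(max(abs(ec$centrality - v)), 1e-8)
  }
})

test_that("reducible matrices are restricted to the largest SCC", {
  # node 3 is a source: it never receives mass
  P <- matrix(c(0, 1, 0,
                1, 0, 0,
                0.5, 0.5, 0), 3L, byrow = TRUE)
  expect_warning(ec <- eigenvector_centrality(P), "SCC")
  expect_equal(ec$scc, c(0L, 1L))
  expect_equal(ec$centrality, c(0.5, 0.5, 0))
})

test_that("damped centrality handles reducible matrices without SCC pruning", {
  P <- matrix(c(0, 1, 0,
                1, 0, 0,
                0.5, 0.5, 0), 3L, byrow = TRUE)
  ec <- eigenvector_centrality(P, damping = 0.85)
  expect_equal(sum(ec$centrality), 1)
  expect_true(all(ec$centrality > 0))
})

test_that("centrality context test flags a shifted syllable", {
  withr::local_seed(23)
  mk <- function(ctx, boost) {
    dplyr::bind_rows(lapply(1:8, function(a) {
      v <- rep(1, 6); v[1] <- boost + runif(1, 0, 0.05)
      tibble::tibble(recording_id = paste0(ctx, a), animal_id = paste0("a", a),
                     context = ctx, syllable = 0:5, centrality = v / sum(v))
    }))
  }
  cent <- dplyr::bind_rows(mk("solitary", 1), mk("dyadic", 3))
  ct <- centrality_context_test(cent)
  expect_true(ct$significant[ct$syllable == 0L])
  expect_error(centrality_context_test(cent[cent$context == "dyadic", ]),
               "2 animals")
})

test_that("edge modulation restricts the family and reports delta", {
  exp <- simulate_experiment(tiny_config(seed = 14L))
  nets <- transition_networks(extract_bouts(exp$sequences), 32L)
  em <- transition_modulation(nets, min_count = 20, dm = c(7L, 10L))
  expect_s3_class(em, "soseq_edge_modulation")
  pooled <- Reduce(`+`, lapply(nets$network, function(nw) nw$counts))
  expect_true(all(pooled[cbind(em$edges$from + 1L, em$edges$to + 1L)] >= 20))
  expect_true(all(abs(em$edges$delta) <= 1))
  expect_identical(em$edges$targets_dm, em$edges$to %in% c(7L, 10L))
  g <- glance(em)
  expect_equal(g$n_edges_tested, nrow(em$edges))
})

test_that("GraphML export writes a parseable graph", {
  exp <- simulate_experiment(tiny_config(seed = 15L))
  nets <- transition_networks(extract_bouts(exp$sequences), 32L)
  em <- transition_modulation(nets, min_count = 20)
  cent <- centrality_table(nets)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(em, cent, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(em$edges))
  expect_true("delta" %in% igraph::edge_attr_names(g))
})
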