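#' Bout-transition probability matrix
#'
#' Counts consecutive bout pairs (current -> next) and row-normalizes so
#' every syllable's outgoing probabilities sum to 1. The diagonal is
#' structurally zero because adjacent bouts always differ. Rows without any
#' outgoing count are flagged empty and left at zero.
#'
#' @param bouts bout tibble for one animal-recording, ordered by `start`.
#' @param n_syllables vocabulary size.
#' @return list of class `soseq_transition_network`: `P` (n x n
#'   probabilities), `counts`, `empty_rows` (0-based ids), plus the
#'   identifiers carried on the bouts.
#' @export
transition_matrix <- function(bouts, n_syllables) {
  if (nrow(bouts) < 2L) abort("need at least 2 bouts")
  bouts <- arrange(bouts, .data$start)
  from <- bouts$syllable[-nrow(bouts)] + 1L
  to <- bouts$syllable[-1L] + 1L
  counts <- matrix(0, n_syllables, n_syllables)
  for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  structure(list(
    P = P, counts = counts, empty_rows = which(rs == 0) - 1L,
    recording_id = bouts$recording_id[1], animal_id = bouts$animal_id[1],
    context = bouts$context[1]
  ), class = "soseq_transition_network")
}

#' Per-animal transition networks for a bout table
#'
#' @param bouts bout tibble covering several animal-recordings.
#' @param n_syllables vocabulary size.
#' @return tibble `recording_id`, `animal_id`, `context`, `network`
#'   (list-column of [transition_matrix()] results).
#' @export
transition_networks <- function(bouts, n_syllables) {
  parts <- bouts %>%
    group_by(.data$recording_id, .data$animal_id, .data$context) %>%
    dplyr::group_split()
  rows <- lapply(parts, function(d) {
    tibble(recording_id = d$recording_id[1], animal_id = d$animal_id[1],
           context = d$context[1],
           network = list(transition_matrix(d, n_syllables)))
  })
  bind_rows(rows)
}

#' Eigenvector centrality of a transition network
#'
#' Dominant left eigenvector of the transition matrix (incoming influence),
#' computed by power iteration and L1-normalized, so for a strongly
#' connected matrix it equals the stationary distribution. Reducible
#' matrices are restricted to the largest strongly connected component
#' (rows renormalized within it) with zeros elsewhere and a warning; an
#' additive damping factor is available as an alternative.
#'
#' @param net a `soseq_transition_network` (or a bare matrix).
#' @param tol L-infinity convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param orientation `"left"` (incoming influence, default) or `"right"`.
#' @param damping optional damping in (0,1); when given, the matrix is
#'   mixed with the uniform matrix as `d*P + (1-d)/n` instead of the SCC
#'   restriction.
#' @return list of class `soseq_centrality`: `centrality` (length-n,
#'   non-negative, sums to 1), `iterations`, `scc` (0-based member ids).
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 1e5,
                                   orientation = c("left", "right"),
                                   damping = NULL) {
  orientation <- match.arg(orientation)
  P <- if (inherits(net, "soseq_transition_network")) net$P else net
  if (any(P < 0)) abort("matrix must be non-negative")
  n <- nrow(P)
  if (orientation == "right") P <- t(P)
  scc_members <- seq_len(n)
  if (!is.null(damping)) {
    P <- damping * P + (1 - damping) / n
  } else {
    g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "directed")
    comp <- igraph::components(g, mode = "strong")
    largest <- which.max(tabulate(comp$membership))
    scc_members <- which(comp$membership == largest)
    if (length(scc_members) < n) {
      warn(sprintf("matrix is reducible; restricting to largest SCC (%d of %d nodes)",
                   length(scc_members), n))
    }
    P <- P[scc_members, scc_members, drop = FALSE]
    rs <- rowSums(P)
    P <- P / ifelse(rs == 0, 1, rs)
  }
  m <- nrow(P)
  c0 <- rep(1 / m, m)
  it <- 0L
  repeat {
    c1 <- as.numeric(c0 %*% P)
    s <- sum(c1)
    if (s == 0) abort("centrality iteration collapsed to zero")
    c1 <- c1 / s
    it <- it + 1L
    if (max(abs(c1 - c0)) < tol) break
    if (it >= max_iter) {
      abort(sprintf(
        "power iteration did not converge in %d iterations (residual %.3g); spectral gap may be tiny",
        max_iter, max(abs(c1 - c0))))
    }
    c0 <- c1
  }
  cent <- rep(0, n)
  cent[scc_members] <- c1
  structure(list(centrality = cent / sum(cent), iterations = it,
                 tol = tol, scc = scc_members - 1L,
                 orientation = orientation),
            class = "soseq_centrality")
}

#' Per-animal centralities for a networks table
#'
#' @param networks output of [transition_networks()].
#' @param ... passed to [eigenvector_centrality()].
#' @return long tibble `recording_id`, `animal_id`, `context`, `syllable`,
#'   `centrality`.
#' @export
centrality_table <- function(networks, ...) {
  rows <- lapply(seq_len(nrow(networks)), function(i) {
    cv <- suppressWarnings(eigenvector_centrality(networks$network[[i]], ...))
    tibble(recording_id = networks$recording_id[i],
           animal_id = networks$animal_id[i],
           context = networks$context[i],
           syllable = seq_along(cv$centrality) - 1L,
           centrality = cv$centrality)
  })
  bind_rows(rows)
}

#' Context contrast of eigenvector centrality
#'
#' Per-syllable two-sided Mann-Whitney U test of per-animal centralities
#' between solitary and dyadic contexts, Bonferroni-corrected across
#' syllables.
#'
#' @param centralities output of [centrality_table()] covering both
#'   contexts.
#' @param alpha significance level.
#' @return tibble with per-syllable test results.
#' @export
centrality_context_test <- function(centralities, alpha = 0.05) {
  wide <- centralities %>%
    tidyr::pivot_wider(names_from = "syllable", values_from = "centrality",
                       names_sort = TRUE)
  per_ctx <- table(wide$context)
  if (length(per_ctx) < 2L || any(per_ctx < 2L)) {
    abort("need at least 2 animals in each context")
  }
  syl_cols <- setdiff(names(wide), c("recording_id", "animal_id", "context"))
  X <- as.matrix(wide[, syl_cols])
  res <- mwu_test_cols(X, wide$context == "dyadic")
  test_result_tbl(res$statistic, res$p_value, "mann_whitney_u",
                  "bonferroni", alpha) %>%
    mutate(syllable = as.integer(syl_cols), .before = 1L)
}

#' Per-edge transition modulation between contexts
#'
#' The edge universe is restricted to edges with pooled transition count at
#' least `min_count` (this bounds the Bonferroni family; testing all n(n-1)
#' edges would be statistically vacuous). Each edge's per-animal transition
#' probability is compared across contexts with a two-sided Mann-Whitney U
#' test, Bonferroni-corrected over the tested edges. `delta` is the mean
#' dyadic minus mean solitary probability (positive = upmodulated in
#' dyadic context).
#'
#' @param networks output of [transition_networks()].
#' @param alpha significance level.
#' @param min_count pooled-count floor for an edge to enter the family.
#' @param dm optional DM syllable ids; adds a `targets_dm` flag and the
#'   fraction of significant edges whose target is DM.
#' @return list of class `soseq_edge_modulation`: `edges` (per-edge
#'   tibble), `targets_dm_fraction` (or `NA` if `dm` is `NULL`).
#' @export
transition_modulation <- function(networks, alpha = 0.05, min_count = 10,
                                  dm = NULL) {
  n <- nrow(networks$network[[1]]$P)
  pooled <- Reduce(`+`, lapply(networks$network, `[[`, "counts"))
  idx <- which(pooled >= min_count, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("no edge reaches the pooled count floor")
  X <- vapply(networks$network,
              function(nw) nw$P[idx],
              numeric(nrow(idx)))
  X <- t(X)                                 # animals x edges
  grp <- networks$context == "dyadic"
  res <- mwu_test_cols(X, grp)
  delta <- colMeans(X[grp, , drop = FALSE]) - colMeans(X[!grp, , drop = FALSE])
  edges <- test_result_tbl(res$statistic, res$p_value, "mann_whitney_u",
                           "bonferroni", alpha) %>%
    mutate(from = idx[, 1] - 1L, to = idx[, 2] - 1L,
           pooled_count = pooled[idx], delta = delta, .before = 1L)
  frac <- NA_real_
  if (!is.null(dm)) {
    edges <- mutate(edges, targets_dm = .data$to %in% dm)
    n_sig <- sum(edges$significant)
    frac <- if (n_sig > 0) sum(edges$significant & edges$targets_dm) / n_sig else NA_real_
  }
  structure(list(edges = edges, targets_dm_fraction = frac, alpha = alpha,
                 min_count = min_count),
            class = "soseq_edge_modulation")
}

#' @export
tidy.soseq_edge_modulation <- function(x, ...) x$edges

#' @export
glance.soseq_edge_modulation <- function(x, ...) {
  tibble(n_edges_tested = nrow(x$edges),
         n_significant = sum(x$edges$significant),
         targets_dm_fraction = x$targets_dm_fraction,
         min_count = x$min_count, alpha = x$alpha)
}

#' Export a context-modulation graph to GraphML
#'
#' Builds a directed graph whose edges carry the probability change
#' (`delta`, signed) and significance flag, and whose nodes carry the
#' centrality change, mirroring the network-figure attributes.
#'
#' @param modulation a `soseq_edge_modulation`.
#' @param centralities output of [centrality_table()].
#' @param path output GraphML file.
#' @return the path, invisibly.
#' @export
export_graphml <- function(modulation, centralities, path) {
  cent_delta <- centralities %>%
    group_by(.data$syllable, .data$context) %>%
    summarise(m = mean(.data$centrality), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "context", values_from = "m") %>%
    mutate(delta_centrality = .data$dyadic - .data$solitary)
  e <- modulation$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to),
               delta = e$delta, significant = e$significant),
    vertices = data.frame(name = as.character(cent_delta$syllable),
                          delta_centrality = cent_delta$delta_centrality)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
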