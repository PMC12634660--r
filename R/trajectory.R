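# Egocentric syllable trajectories and shape comparison.

rotate2 <- function(xy, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  xy %*% t(R)
}

# align one instance: translate onset to origin, rotate onset heading to +x,
# resample to L points by linear interpolation in normalized time
align_instance <- function(x, y, L) {
  n <- length(x)
  if (n < 2L || anyNA(x) || anyNA(y)) return(NULL)
  xy <- cbind(x - x[1], y - y[1])
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  nz <- which(dx != 0 | dy != 0)
  if (!length(nz)) {
    head_v <- c(1, 0)               # fully stationary instance: identity frame
  } else {
    k <- if (dx[1] != 0 || dy[1] != 0) 1L else nz[1]
    head_v <- c(dx[k], dy[k])
  }
  theta <- atan2(head_v[2], head_v[1])
  xy <- rotate2(xy, -theta)
  t0 <- seq(0, 1, length.out = n)
  t1 <- seq(0, 1, length.out = L)
  cbind(approx(t0, xy[, 1], t1)$y, approx(t0, xy[, 2], t1)$y)
}

heading_change <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  keep <- dx != 0 | dy != 0
  a <- atan2(dy[keep], dx[keep])
  if (length(a) < 2L) return(0)
  d <- diff(a)
  d <- (d + pi) %% (2 * pi) - pi
  sum(d)
}

#' Mean egocentric trajectory of one syllable
#'
#' Every bout instance of the syllable is translated so its onset is the
#' origin, rotated so the onset heading (displacement over the first two
#' frames, falling back to the first nonzero displacement) points along +x,
#' and linearly resampled to `L` points; the mean over instances is
#' returned together with per-syllable movement metrics (mean net
#' displacement, path length and signed net heading change over instances).
#'
#' @param bouts bout tibble restricted to one syllable.
#' @param tracks track tibble covering the bouts' recordings.
#' @param L resample length in points (default 10, the median bout length
#'   in frames).
#' @return list: `path` (L x 2 matrix, `path[1,] = (0,0)`), `n_instances`,
#'   `net_displacement`, `path_length`, `net_heading_change`.
#' @export
egocentric_mean_trajectory <- function(bouts, tracks, L = 10L) {
  key <- paste(tracks$recording_id, tracks$animal_id)
  xs <- setNames(tracks$x, key); ys <- setNames(tracks$y, key)
  acc <- matrix(0, L, 2L)
  n_ok <- 0L
  net <- len <- turn <- 0
  for (i in seq_len(nrow(bouts))) {
    k <- paste(bouts$recording_id[i], bouts$animal_id[i])
    x <- xs[[k]]; y <- ys[[k]]
    if (is.null(x)) next
    idx <- (bouts$start[i] + 1L):bouts$end[i]
    if (max(idx) > length(x) || length(idx) < 2L) next
    al <- align_instance(x[idx], y[idx], L)
    if (is.null(al)) next
    acc <- acc + al
    n_ok <- n_ok + 1L
    net <- net + sqrt(sum((al[L, ] - al[1, ])^2))
    len <- len + sum(sqrt(rowSums(diff(al)^2)))
    turn <- turn + heading_change(x[idx], y[idx])
  }
  if (n_ok == 0L) abort("no usable instances for this syllable")
  list(path = acc / n_ok, n_instances = n_ok,
       net_displacement = net / n_ok, path_length = len / n_ok,
       net_heading_change = turn / n_ok)
}

#' Egocentric trajectories for all syllables
#'
#' @param bouts bout tibble (all syllables).
#' @param tracks track tibble.
#' @param L resample length.
#' @param min_instances syllables with fewer usable instances are dropped.
#' @return tibble: `syllable`, `n_instances`, `net_displacement`,
#'   `path_length`, `net_heading_change`, `path` (list-column of L x 2
#'   matrices).
#' @export
syllable_trajectories <- function(bouts, tracks, L = 10L, min_instances = 1L) {
  syls <- sort(unique(bouts$syllable))
  rows <- lapply(syls, function(s) {
    tr <- tryCatch(
      egocentric_mean_trajectory(bouts[bouts$syllable == s, ], tracks, L),
      error = function(e) NULL
    )
    if (is.null(tr) || tr$n_instances < min_instances) return(NULL)
    tibble(syllable = s, n_instances = tr$n_instances,
           net_displacement = tr$net_displacement,
           path_length = tr$path_length,
           net_heading_change = tr$net_heading_change,
           path = list(tr$path))
  })
  bind_rows(rows)
}

#' Cosine distance between two vectors
#'
#' `1 - u.v / (|u||v|)`, in `[0, 2]`. Zero vectors are an error.
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine distance undefined for zero vectors")
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2)
}

#' Inter-syllable trajectory similarity dendrogram
#'
#' Pairwise cosine distances between flattened mean egocentric trajectories,
#' clustered agglomeratively with average linkage; the tree is also
#' serialized in Newick format.
#'
#' @param trajectories output of [syllable_trajectories()] with >= 2 rows.
#' @return list of class `soseq_dendrogram`: `dist` (symmetric matrix, zero
#'   diagonal), `hclust`, `newick` (string).
#' @export
similarity_dendrogram <- function(trajectories) {
  n <- nrow(trajectories)
  if (n < 2L) abort("need at least 2 syllables")
  V <- t(vapply(trajectories$path, as.numeric,
                numeric(2L * nrow(trajectories$path[[1]]))))
  D <- matrix(0, n, n,
              dimnames = list(trajectories$syllable, trajectories$syllable))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- cosine_distance(V[i, ], V[j, ])
    }
  }
  if (anyNA(D)) {
    bad <- which(is.na(D), arr.ind = TRUE)[1, ]
    abort(sprintf("NaN distance between syllables %s and %s",
                  rownames(D)[bad[1]], colnames(D)[bad[2]]))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(dist = D, hclust = hc, newick = newick),
            class = "soseq_dendrogram")
}

#' Movement-metric contrast between DM and DU syllables
#'
#' One-sided Mann-Whitney U tests compare the DM and DU syllable groups on
#' each movement metric (net displacement and absolute net heading change
#' by default), Bonferroni-corrected across metrics. The default directions
#' encode the expectation that dyadic-modulated syllables are stationary
#' and undirected: lower net displacement, larger absolute heading change.
#'
#' @param trajectories output of [syllable_trajectories()].
#' @param dm integer ids of the DM set.
#' @param alpha significance level.
#' @param directions named character vector of alternatives per metric
#'   (`"less"` means DM < DU).
#' @return tibble with one row per metric.
#' @export
movement_class_test <- function(trajectories, dm, alpha = 0.05,
                                directions = c(net_displacement = "less",
                                               abs_heading_change = "greater")) {
  is_dm <- trajectories$syllable %in% dm
  if (!any(is_dm) || all(is_dm)) abort("both DM and DU sets must be non-empty")
  metrics <- tibble(
    net_displacement = trajectories$net_displacement,
    abs_heading_change = abs(trajectories$net_heading_change)
  )[, names(directions), drop = FALSE]
  rows <- imap(directions, function(dir, m) {
    res <- mwu_test_cols(matrix(metrics[[m]], ncol = 1L), is_dm,
                         alternative = dir)
    tibble(metric = m, alternative = dir,
           statistic = res$statistic, p_raw = res$p_value)
  })
  bind_rows(rows) %>%
    mutate(p_adjusted = adjust_p(.data$p_raw, "bonferroni"),
           method = "mann_whitney_u", correction = "bonferroni",
           significant = .data$p_adjusted < alpha)
}
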