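# PCA on per-track syllable / syntax proportions and context separation.

#' Per-track syllable feature matrix
#'
#' One row per animal-recording ("track"), one column per syllable, values
#' the frame (default) or onset proportions.
#'
#' @param proportions output of [syllable_proportions()].
#' @param value `"frame_prop"` or `"onset_prop"`.
#' @return wide tibble with id columns `recording_id`, `animal_id`,
#'   `context`, `light_cycle`.
#' @export
syllable_feature_matrix <- function(proportions, value = "frame_prop") {
  proportions %>%
    select("recording_id", "animal_id", "context", "light_cycle",
           "syllable", v = dplyr::all_of(value)) %>%
    mutate(syllable = paste0("syl_", .data$syllable)) %>%
    tidyr::pivot_wider(names_from = "syllable", values_from = "v",
                       values_fill = 0)
}

#' Per-track syntax feature matrix
#'
#' One row per animal-recording, one column per retained syntax (those with
#' at least `min_occurrences` pooled occurrences), values per-track onset
#' proportions among the retained set.
#'
#' @param syntaxes output of [extract_syntaxes()].
#' @param min_occurrences pooled occurrence floor for a syntax column.
#' @return wide tibble as in [syllable_feature_matrix()]; syntax columns
#'   are named `"s1,s2,s3"`.
#' @export
syntax_feature_matrix <- function(syntaxes, min_occurrences = 50L) {
  syntaxes$key <- syntax_key(syntaxes)
  keep <- names(which(table(syntaxes$key) >= min_occurrences))
  if (!length(keep)) abort("no syntax reaches the occurrence floor")
  light <- if ("light_cycle" %in% names(syntaxes)) syntaxes$light_cycle else "normal"
  syntaxes %>%
    mutate(light_cycle = light) %>%
    filter(.data$key %in% keep) %>%
    group_by(.data$recording_id, .data$animal_id, .data$context,
             .data$light_cycle, .data$key) %>%
    summarise(n = dplyr::n(), .groups = "drop_last") %>%
    mutate(v = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-"n") %>%
    tidyr::pivot_wider(names_from = "key", values_from = "v",
                       values_fill = 0)
}

#' Syntax columns dominated by DM syllables
#'
#' A DM syntax contains at least 2 DM syllables among its three positions.
#'
#' @param feature_names syntax column names (`"s1,s2,s3"`).
#' @param dm DM syllable ids.
#' @return logical vector over `feature_names`.
#' @export
is_dm_syntax <- function(feature_names, dm) {
  map_lgl(strsplit(feature_names, ","), function(tr) {
    sum(as.integer(tr) %in% dm) >= 2L
  })
}

#' PCA of per-track behavioral features
#'
#' Centered (not scaled by default, since proportions share one scale)
#' principal component analysis via singular value decomposition, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param features wide tibble from [syllable_feature_matrix()] or
#'   [syntax_feature_matrix()].
#' @param center,scale. passed to [stats::prcomp()].
#' @return list of class `soseq_pca`: `loadings` (features x components,
#'   unit-norm columns), `var_explained`, `scores` (tibble with id
#'   columns), `feature_names`.
#' @export
pca_features <- function(features, center = TRUE, scale. = FALSE) {
  id_cols <- intersect(c("recording_id", "animal_id", "context", "light_cycle"),
                       names(features))
  X <- as.matrix(features[, setdiff(names(features), id_cols)])
  if (nrow(X) < 3L) abort("need at least 3 tracks")
  if (all(apply(X, 2L, var) == 0)) abort("feature matrix has zero variance")
  pc <- prcomp(X, center = center, scale. = scale.)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    loadings = rot, var_explained = ve,
    scores = bind_cols(features[, id_cols], as_tibble(scores)),
    feature_names = colnames(X), center = center, scale = scale.
  ), class = "soseq_pca")
}

#' @export
tidy.soseq_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "feature") %>%
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.soseq_pca <- function(x, ...) {
  tibble(n_components = length(x$var_explained),
         var_explained_pc1 = x$var_explained[1],
         var_explained_first5 = sum(head(x$var_explained, 5)))
}

#' DM vs DU loading contrast per principal component
#'
#' One-sided Mann-Whitney U test of the absolute loadings of DM features
#' against DU features for each of the first `n_components` components
#' (alternative: DM loadings larger), Bonferroni-corrected across the
#' tested components.
#'
#' @param pca a `soseq_pca`.
#' @param dm_features logical vector over features (TRUE = DM).
#' @param n_components components tested.
#' @param alpha significance level.
#' @return tibble with one row per component.
#' @export
loading_contrast <- function(pca, dm_features, n_components = 5L,
                             alpha = 0.05) {
  if (!any(dm_features) || all(dm_features)) {
    abort("both feature partitions must be non-empty")
  }
  n_components <- min(n_components, ncol(pca$loadings))
  L <- abs(pca$loadings[, seq_len(n_components), drop = FALSE])
  res <- mwu_test_cols(L, dm_features, alternative = "greater")
  test_result_tbl(res$statistic, res$p_value, "mann_whitney_u",
                  "bonferroni", alpha) %>%
    mutate(component = seq_len(n_components),
           var_explained = pca$var_explained[seq_len(n_components)],
           .before = 1L)
}

#' Group separation of PCA scores
#'
#' Mean silhouette width of the tracks in the plane of the first two
#' principal components, computed for each requested grouping. Used to
#' compare how strongly context versus light cycle structures the score
#' scatter (the silhouette index is an artifact-level summary of the
#' scatter, not a classifier).
#'
#' @param pca a `soseq_pca`.
#' @param groupings character vector of id columns to evaluate.
#' @return tibble `grouping`, `silhouette`, `n_groups`.
#' @export
context_separation <- function(pca, groupings = c("context", "light_cycle")) {
  S <- as.matrix(pca$scores[, c("PC1", "PC2")])
  rows <- lapply(groupings, function(g) {
    lab <- pca$scores[[g]]
    if (is.null(lab)) abort(sprintf("grouping column '%s' not found", g))
    tab <- table(lab)
    if (length(tab) < 2L) abort(sprintf("grouping '%s' has a single level", g))
    if (any(tab < 2L)) abort(sprintf("grouping '%s' has a level with < 2 tracks", g))
    sil <- cluster::silhouette(as.integer(factor(lab)), stats::dist(S))
    tibble(grouping = g, silhouette = mean(sil[, "sil_width"]),
           n_groups = length(tab))
  })
  bind_rows(rows)
}
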