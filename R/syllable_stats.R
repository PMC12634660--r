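#' Extract syllable bouts from frame-wise label sequences
#'
#' A bout is a maximal run of consecutive frames carrying the same syllable
#' label. Runs of `-1` (missing) are skipped and break adjacency, so two
#' equal-label runs separated by a missing stretch become two bouts.
#' Intervals are half-open `[start, end)` in 0-based frames.
#'
#' @param sequences a sequence tibble (see [syllable_sequence()]), any
#'   number of rows.
#' @return tibble with one row per bout: `recording_id`, `animal_id`,
#'   `context`, `light_cycle`, `syllable`, `start`, `end`, `duration`.
#' @export
extract_bouts <- function(sequences) {
  out <- lapply(seq_len(nrow(sequences)), function(i) {
    labels <- sequences$labels[[i]]
    if (all(labels == -1L)) {
      abort(sprintf("sequence %s/%s has no assigned frames",
                    sequences$recording_id[i], sequences$animal_id[i]))
    }
    iv <- rle_intervals(labels)
    iv <- iv[iv$syllable != -1L, , drop = FALSE]
    tibble(
      recording_id = sequences$recording_id[i],
      animal_id = sequences$animal_id[i],
      context = sequences$context[i],
      light_cycle = sequences$light_cycle[i],
      syllable = iv$syllable, start = iv$start, end = iv$end,
      duration = iv$end - iv$start
    )
  })
  bind_rows(out)
}

#' Onset and frame proportions per animal-recording
#'
#' The onset (bout) proportion of a syllable is the fraction of bouts it
#' accounts for, regardless of bout length; the frame proportion is the
#' fraction of non-missing frames. Both vectors sum to 1 per
#' animal-recording.
#'
#' @param bouts bout tibble from [extract_bouts()].
#' @param n_syllables vocabulary size (syllables `0..n_syllables-1` appear
#'   in the output even with zero counts).
#' @return long tibble: `recording_id`, `animal_id`, `context`,
#'   `light_cycle`, `syllable`, `n_bouts`, `n_frames`, `onset_prop`,
#'   `frame_prop`.
#' @export
syllable_proportions <- function(bouts, n_syllables) {
  if (nrow(bouts) == 0L) abort("no bouts supplied")
  syl_levels <- factor(bouts$syllable, levels = 0:(n_syllables - 1L))
  bouts %>%
    mutate(syllable = syl_levels) %>%
    group_by(.data$recording_id, .data$animal_id, .data$context,
             .data$light_cycle, .data$syllable, .drop = FALSE) %>%
    summarise(n_bouts = dplyr::n(), n_frames = sum(.data$duration),
              .groups = "drop_last") %>%
    mutate(onset_prop = .data$n_bouts / sum(.data$n_bouts),
           frame_prop = .data$n_frames / sum(.data$n_frames)) %>%
    ungroup() %>%
    filter(!is.na(.data$recording_id)) %>%
    mutate(syllable = as.integer(as.character(.data$syllable)))
}

#' Retain syllables above the onset-proportion threshold
#'
#' Pools onset counts over all animal-recordings and retains syllables whose
#' pooled onset proportion is strictly greater than `threshold` (0.5% by
#' default, the retention rule applied to the decomposition output).
#' Retained ids are returned in descending pooled-proportion order together
#' with the old-to-new id mapping.
#'
#' @param proportions output of [syllable_proportions()].
#' @param threshold pooled onset-proportion cutoff (strict).
#' @return tibble `syllable` (original id), `pooled_onset_prop`, `new_id`
#'   (dense rank by decreasing proportion), restricted to retained ids.
#' @export
filter_syllables <- function(proportions, threshold = 0.005) {
  pooled <- proportions %>%
    group_by(.data$syllable) %>%
    summarise(n_bouts = sum(.data$n_bouts), .groups = "drop") %>%
    mutate(pooled_onset_prop = .data$n_bouts / sum(.data$n_bouts)) %>%
    arrange(dplyr::desc(.data$pooled_onset_prop))
  keep <- pooled %>% filter(.data$pooled_onset_prop > threshold)
  if (nrow(keep) == 0L) {
    abort("no syllable exceeds the onset threshold; lower `threshold`")
  }
  keep %>% mutate(new_id = row_number() - 1L) %>%
    select("syllable", "pooled_onset_prop", "new_id")
}

#' Total distance moved along a centroid track
#'
#' Sum of Euclidean frame-to-frame displacements in mm; displacements
#' involving a missing frame are skipped.
#'
#' @param tracks a track tibble (see [centroid_track()]).
#' @return tibble `recording_id`, `animal_id`, `distance_mm`.
#' @export
distance_moved <- function(tracks) {
  out <- map_dbl(seq_len(nrow(tracks)), function(i) {
    x <- tracks$x[[i]]; y <- tracks$y[[i]]
    if (all(is.na(x))) {
      abort(sprintf("track %s/%s has no valid frames",
                    tracks$recording_id[i], tracks$animal_id[i]))
    }
    dx <- diff(x); dy <- diff(y)
    sum(sqrt(dx^2 + dy^2), na.rm = TRUE)
  })
  tibble(recording_id = tracks$recording_id, animal_id = tracks$animal_id,
         distance_mm = out)
}

#' Context-modulation test for syllable onset proportions
#'
#' For every syllable, a two-sided Mann-Whitney U test compares per-animal
#' onset proportions between solitary and dyadic contexts;
#' Benjamini-Hochberg correction is applied across syllables. Significant
#' syllables form the dyadic-modulated (DM) set, the rest the DU set.
#' Syllables absent from every animal are skipped and flagged.
#'
#' @param proportions output of [syllable_proportions()] covering both
#'   contexts.
#' @param alpha significance level.
#' @param value which proportion to test (`"onset_prop"` or `"frame_prop"`).
#' @return object of class `soseq_context_modulation`: list with `tests`
#'   (per-syllable tibble), `dm` and `du` (integer id vectors), `alpha`.
#' @export
compare_contexts <- function(proportions, alpha = 0.05, value = "onset_prop") {
  wide <- proportions %>%
    select("recording_id", "animal_id", "context", "syllable",
           value = dplyr::all_of(value)) %>%
    tidyr::pivot_wider(names_from = "syllable", values_from = "value",
                       names_sort = TRUE)
  per_ctx <- table(wide$context)
  if (length(per_ctx) < 2L || any(per_ctx < 2L)) {
    abort("need at least 2 animals in each context")
  }
  syl_cols <- setdiff(names(wide), c("recording_id", "animal_id", "context"))
  X <- as.matrix(wide[, syl_cols])
  grp <- wide$context == "dyadic"
  absent <- colSums(X, na.rm = TRUE) == 0
  res <- mwu_test_cols(X[, !absent, drop = FALSE], grp)
  tests <- test_result_tbl(res$statistic, res$p_value,
                           "mann_whitney_u", "benjamini_hochberg", alpha) %>%
    mutate(syllable = as.integer(syl_cols[!absent]), .before = 1L)
  skipped <- as.integer(syl_cols[absent])
  if (length(skipped)) {
    warn(sprintf("syllable(s) absent everywhere, test skipped: %s",
                 paste(skipped, collapse = ", ")))
  }
  dm <- sort(tests$syllable[tests$significant])
  du <- sort(c(setdiff(tests$syllable, dm), skipped))
  structure(list(tests = tests, dm = dm, du = du, skipped = skipped,
                 alpha = alpha, value = value),
            class = "soseq_context_modulation")
}

#' @export
print.soseq_context_modulation <- function(x, ...) {
  cat(sprintf("<context modulation: %d DM, %d DU syllables (alpha = %g)>\n",
              length(x$dm), length(x$du), x$alpha))
  cat("DM:", paste(x$dm, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.soseq_context_modulation <- function(x, ...) x$tests

#' @export
glance.soseq_context_modulation <- function(x, ...) {
  tibble(n_syllables = nrow(x$tests) + length(x$skipped),
         n_dm = length(x$dm), n_du = length(x$du),
         n_skipped = length(x$skipped), alpha = x$alpha)
}

# frames covered by any interval of a half-open interval tibble
interval_membership <- function(start, end, n_frames) {
  inside <- logical(n_frames)
  for (i in seq_along(start)) {
    lo <- max(start[i] + 1L, 1L)
    hi <- min(end[i], n_frames)
    if (lo <= hi) inside[lo:hi] <- TRUE
  }
  inside
}

#' Contact association of syllable onsets
#'
#' For each syllable, a 2x2 contingency table (onsets of this syllable vs
#' all other syllables, onset frame inside vs outside active contact) is
#' tested with a chi-square test, Bonferroni-corrected across tested
#' syllables. A two-way ANOVA (syllable x contact) on per-animal onset
#' proportions is also reported. The onset is assigned to the bout's first
#' frame.
#'
#' @param bouts dyadic bout tibble.
#' @param annotations pooled annotation tibble.
#' @param n_frames frames per recording (for the in/out membership mask).
#' @param alpha significance level.
#' @param contact_type which contact type defines "inside".
#' @param syllables ids to test (e.g. the DM set); default all present.
#' @return list of class `soseq_contact_association`: `tests` (per-syllable
#'   tibble with odds ratios), `anova` (tidy two-way ANOVA table), `alpha`.
#' @export
contact_association <- function(bouts, annotations, n_frames, alpha = 0.05,
                                contact_type = "active", syllables = NULL) {
  ann <- annotations[annotations$contact_type == contact_type, ]
  if (nrow(ann) == 0L) abort("no contact bouts of the requested type")
  recs <- unique(bouts$recording_id)
  masks <- lapply(recs, function(r) {
    a <- ann[ann$recording_id == r, ]
    interval_membership(a$start, a$end, n_frames)
  })
  names(masks) <- recs
  onset_in <- map_lgl(seq_len(nrow(bouts)), function(i) {
    m <- masks[[bouts$recording_id[i]]]
    f <- bouts$start[i] + 1L
    !is.null(m) && f <= length(m) && m[f]
  })
  if (!any(onset_in)) abort("no syllable onsets fall inside contact")
  if (is.null(syllables)) syllables <- sort(unique(bouts$syllable))
  tab <- lapply(syllables, function(s) {
    is_s <- bouts$syllable == s
    m <- matrix(c(sum(is_s & onset_in), sum(!is_s & onset_in),
                  sum(is_s & !onset_in), sum(!is_s & !onset_in)), 2L)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(tibble(syllable = s, statistic = NA_real_, p_raw = NA_real_,
                    odds_ratio = NA_real_))
    }
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    or <- (m[1, 1] * m[2, 2]) / max(m[1, 2] * m[2, 1], .Machine$double.eps)
    tibble(syllable = s, statistic = unname(ct$statistic),
           p_raw = ct$p.value, odds_ratio = or)
  }) %>% bind_rows()
  tests <- tab %>%
    mutate(p_adjusted = adjust_p(.data$p_raw, "bonferroni"),
           method = "chi2_contingency", correction = "bonferroni",
           significant = !is.na(.data$p_adjusted) & .data$p_adjusted < alpha)

  # two-way ANOVA on per-animal onset proportions in/out of contact
  cells <- bouts %>%
    mutate(in_contact = onset_in) %>%
    filter(.data$syllable %in% syllables) %>%
    group_by(.data$recording_id, .data$animal_id, .data$syllable,
             .data$in_contact) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>%
    group_by(.data$recording_id, .data$animal_id, .data$in_contact) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup()
  an <- aov(prop ~ factor(syllable) * in_contact, data = cells)
  an_tab <- as_tibble(summary(an)[[1]], rownames = "term") %>%
    rename(df = "Df", sum_sq = "Sum Sq", mean_sq = "Mean Sq",
           statistic = "F value", p_value = "Pr(>F)") %>%
    mutate(term = stringr::str_trim(.data$term))
  structure(list(tests = tests, anova = an_tab, alpha = alpha,
                 contact_type = contact_type),
            class = "soseq_contact_association")
}

#' @export
tidy.soseq_contact_association <- function(x, ...) x$tests

#' @export
glance.soseq_contact_association <- function(x, ...) {
  tibble(n_tested = sum(!is.na(x$tests$p_raw)),
         n_significant = sum(x$tests$significant, na.rm = TRUE),
         alpha = x$alpha, contact_type = x$contact_type)
}

#' Inter-mouse distance series for a recording
#'
#' Frame-wise Euclidean distance between the two animals of a dyadic
#' recording; symmetric in the two tracks.
#'
#' @param tracks two-row track tibble (one dyadic recording).
#' @return numeric vector of distances (mm).
#' @export
imd_series <- function(tracks) {
  if (nrow(tracks) != 2L) abort("imd_series needs exactly two tracks")
  if (length(tracks$x[[1]]) != length(tracks$x[[2]])) {
    abort("paired tracks must have equal length")
  }
  sqrt((tracks$x[[1]] - tracks$x[[2]])^2 + (tracks$y[[1]] - tracks$y[[2]])^2)
}

#' Distance-quartile association of syllable onsets
#'
#' Each bout onset is assigned the inter-mouse distance at its start frame;
#' quartile edges come from the pooled distance distribution over all
#' supplied recordings. Returns per-syllable onset proportions per quartile
#' and a two-way ANOVA (syllable x quartile) on the per-animal proportions.
#'
#' @param bouts dyadic bout tibble.
#' @param imd_by_recording named list of per-recording distance series.
#' @param alpha significance level (reported with the ANOVA).
#' @return list of class `soseq_quartile_association`: `table` (proportions
#'   per quartile), `edges` (3 inner quartile edges, mm), `anova`.
#' @export
quartile_association <- function(bouts, imd_by_recording, alpha = 0.05) {
  pooled <- unlist(imd_by_recording, use.names = FALSE)
  edges <- quantile(pooled, c(0.25, 0.5, 0.75), names = FALSE)
  if (length(unique(edges)) < 3L || diff(range(pooled)) == 0) {
    abort("degenerate quartiles: inter-mouse distance nearly constant")
  }
  onset_imd <- map_dbl(seq_len(nrow(bouts)), function(i) {
    s <- imd_by_recording[[bouts$recording_id[i]]]
    f <- bouts$start[i] + 1L
    if (is.null(s) || f > length(s)) NA_real_ else s[f]
  })
  q <- cut(onset_imd, c(-Inf, edges, Inf), labels = FALSE)
  d <- bouts %>%
    mutate(quartile = q) %>%
    filter(!is.na(.data$quartile))
  tab <- d %>%
    group_by(.data$quartile, .data$syllable) %>%
    summarise(n = dplyr::n(), .groups = "drop_last") %>%
    mutate(onset_prop = .data$n / sum(.data$n)) %>%
    ungroup()
  cells <- d %>%
    group_by(.data$recording_id, .data$animal_id, .data$quartile,
             .data$syllable) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>%
    group_by(.data$recording_id, .data$animal_id, .data$quartile) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup()
  an <- aov(prop ~ factor(syllable) * factor(quartile), data = cells)
  an_tab <- as_tibble(summary(an)[[1]], rownames = "term") %>%
    rename(df = "Df", sum_sq = "Sum Sq", mean_sq = "Mean Sq",
           statistic = "F value", p_value = "Pr(>F)") %>%
    mutate(term = stringr::str_trim(.data$term))
  structure(list(table = tab, edges = edges, anova = an_tab, alpha = alpha),
            class = "soseq_quartile_association")
}

#' @export
tidy.soseq_quartile_association <- function(x, ...) x$table
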