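#' Extract length-k syntaxes from bout sequences
#'
#' A syntax is an ordered window of `k` consecutive bout labels (stride 1,
#' overlapping). With the default `k = 3` and a median bout length of 10
#' frames a syntax spans roughly one second of behavior. Occurrences carry
#' the frame interval from the first bout's start to the last bout's end.
#'
#' @param bouts bout tibble (any number of animal-recordings).
#' @param k syntax length in bouts.
#' @return tibble `recording_id`, `animal_id`, `context`, `s1..sk`,
#'   `start`, `end`.
#' @export
extract_syntaxes <- function(bouts, k = 3L) {
  parts <- bouts %>%
    group_by(.data$recording_id, .data$animal_id, .data$context) %>%
    dplyr::group_split()
  rows <- lapply(parts, function(d) {
    d <- arrange(d, .data$start)
    n <- nrow(d)
    if (n < k) abort(sprintf("fewer than %d bouts in %s/%s", k,
                             d$recording_id[1], d$animal_id[1]))
    m <- n - k + 1L
    out <- tibble(recording_id = d$recording_id[1],
                  animal_id = d$animal_id[1], context = d$context[1])
    for (j in seq_len(k)) {
      out <- cbind(out, stats::setNames(
        tibble(x = d$syllable[j:(j + m - 1L)]), paste0("s", j)))
    }
    out$start <- d$start[1:m]
    out$end <- d$end[k:n]
    as_tibble(out)
  })
  bind_rows(rows)
}

#' Hamming distance between two equal-length label sequences
#'
#' Number of positions at which the sequences differ; substitutions only,
#' no rearrangements. A syntax family is the set of syntaxes within
#' distance 1 of a reference triple (so `(9,0,10)` belongs to the family
#' `(9,0,5)` but `(0,5,10)` does not).
#'
#' @param a,b integer vectors of equal length.
#' @return integer distance in `0..length(a)`.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) abort("sequences must have equal length")
  sum(a != b)
}

#' Family membership of syntax occurrences
#'
#' @param syntaxes output of [extract_syntaxes()] (k = 3).
#' @param reference reference triple.
#' @param max_distance membership radius (1 by default).
#' @return logical vector over rows of `syntaxes`.
#' @export
is_family_member <- function(syntaxes, reference, max_distance = 1L) {
  d <- (syntaxes$s1 != reference[1]) + (syntaxes$s2 != reference[2]) +
    (syntaxes$s3 != reference[3])
  d <= max_distance
}

syntax_key <- function(syntaxes) {
  paste(syntaxes$s1, syntaxes$s2, syntaxes$s3, sep = ",")
}

#' Contact-aligned syntax z-score time-course
#'
#' Syntax onset frequencies (per-onset share among all syntax onsets at an
#' offset) are aligned to qualifying contact-bout starts and transformed
#' to z-scores using the baseline window from 100 ms to 50 ms before
#' onset (frames -3..-1 at 25 Hz, rounded outward). The baseline standard
#' deviation is floored at the binomial sampling error of the
#' Laplace-smoothed baseline frequency, so syntaxes absent from the short
#' baseline window are not spuriously masked; syntaxes with no onsets in
#' the whole window are skipped. Significance converts z to a two-sided
#' normal p-value with Benjamini-Hochberg correction across
#' (syntax, bin) pairs; syntaxes are ranked by peak post-onset z.
#'
#' @param syntaxes output of [extract_syntaxes()] for the dyadic context.
#' @param annotations pooled annotation tibble.
#' @param contact_type `"active"` or `"passive"`.
#' @param pre_window,post_window offsets followed around onset (frames).
#' @param baseline baseline offset range, inclusive frames.
#' @param min_onsets syntaxes with fewer total onsets in the window are not
#'   tested.
#' @param alpha significance level.
#' @param top_k number of top-ranked syntaxes reported.
#' @return list of class `soseq_syntax_timecourse`: `zscores` (long tibble
#'   syntax x bin), `ranking`, `top` (character keys), `n_qualifying`.
#' @export
zscore_timecourse <- function(syntaxes, annotations, contact_type = "active",
                              pre_window = 125L, post_window = 250L,
                              baseline = c(-3L, -1L), min_onsets = 10L,
                              alpha = 0.05, top_k = 4L) {
  ann <- qualifying_bouts(annotations, contact_type, pre_window)
  if (nrow(ann) == 0L) abort("no qualifying contact bouts")
  # offset of each syntax onset relative to each qualifying bout start
  sy <- syntaxes
  key <- syntax_key(sy)
  offs <- list(); keys <- list()
  for (r in unique(ann$recording_id)) {
    starts <- ann$start[ann$recording_id == r]
    s_rec <- which(sy$recording_id == r)
    if (!length(s_rec) || !length(starts)) next
    onset <- sy$start[s_rec]
    for (b in starts) {
      rel <- onset - b
      inw <- rel >= -pre_window & rel < post_window
      offs[[length(offs) + 1L]] <- rel[inw]
      keys[[length(keys) + 1L]] <- key[s_rec][inw]
    }
  }
  off <- unlist(offs); kk <- unlist(keys)
  if (!length(off)) abort("no syntax onsets fall in the alignment window")
  tot_per_off <- table(factor(off, levels = seq.int(-pre_window, post_window - 1L)))
  tot <- as.numeric(tot_per_off)
  names(tot) <- names(tot_per_off)
  counts <- table(kk)
  tested <- names(counts)[counts >= min_onsets]
  if (!length(tested)) abort("no syntax reaches the onset floor; lower min_onsets")
  offsets <- seq.int(-pre_window, post_window - 1L)
  base_idx <- which(offsets >= baseline[1] & offsets <= baseline[2])
  rows <- lapply(tested, function(s) {
    cs <- table(factor(off[kk == s], levels = offsets))
    f <- as.numeric(cs) / pmax(tot, 1)
    f[tot == 0] <- NA_real_
    fb <- f[base_idx]
    mu <- mean(fb, na.rm = TRUE)
    n_base <- sum(tot[base_idx])
    f_lap <- (sum(as.numeric(cs)[base_idx]) + 1) / (n_base + 2)
    sd_floor <- sqrt(f_lap * (1 - f_lap) / max(n_base / length(base_idx), 1))
    s_emp <- sd(fb, na.rm = TRUE)
    s_use <- max(s_emp, sd_floor, na.rm = TRUE)
    if (!is.finite(s_use) || s_use == 0) return(NULL)
    tibble(syntax = s, offset = offsets, frequency = f,
           z = (f - mu) / s_use)
  })
  zs <- bind_rows(rows)
  zs$p_raw <- 2 * pnorm(-abs(zs$z))
  tested_mask <- !is.na(zs$p_raw)
  zs$p_adjusted <- NA_real_
  zs$p_adjusted[tested_mask] <- adjust_p(zs$p_raw[tested_mask], "benjamini_hochberg")
  zs$significant <- !is.na(zs$p_adjusted) & zs$p_adjusted < alpha
  ranking <- zs %>%
    filter(.data$offset >= 0) %>%
    group_by(.data$syntax) %>%
    summarise(peak_z = max(.data$z, na.rm = TRUE),
              any_significant = any(.data$significant), .groups = "drop") %>%
    arrange(dplyr::desc(.data$peak_z))
  structure(list(zscores = zs, ranking = ranking,
                 top = head(ranking$syntax, top_k),
                 n_qualifying = nrow(ann), contact_type = contact_type,
                 alpha = alpha),
            class = "soseq_syntax_timecourse")
}

#' @export
tidy.soseq_syntax_timecourse <- function(x, ...) x$zscores

#' @export
glance.soseq_syntax_timecourse <- function(x, ...) {
  tibble(contact_type = x$contact_type,
         n_qualifying = x$n_qualifying,
         n_syntaxes_tested = nrow(x$ranking),
         n_syntaxes_significant = sum(x$ranking$any_significant),
         top = paste(x$top, collapse = " | "))
}

#' Per-frame syntax-family occupancy
#'
#' A frame belongs to a family iff it lies inside the span of any syntax
#' occurrence (by either animal of the recording) whose triple is within
#' Hamming distance 1 of the family's reference.
#'
#' @param syntaxes output of [extract_syntaxes()] for one recording.
#' @param reference family reference triple.
#' @param n_frames recording length.
#' @return logical vector of length `n_frames`.
#' @export
family_occupancy <- function(syntaxes, reference, n_frames) {
  mem <- is_family_member(syntaxes, reference)
  occ <- logical(n_frames)
  s <- syntaxes$start[mem]; e <- syntaxes$end[mem]
  for (i in seq_along(s)) {
    lo <- max(s[i] + 1L, 1L); hi <- min(e[i], n_frames)
    if (lo <= hi) occ[lo:hi] <- TRUE
  }
  occ
}

#' Rolling-window relation between distance change and family occupancy
#'
#' For every rolling window of `window` frames the change in inter-mouse
#' distance (CID, end minus start) is paired with the fraction of window
#' frames spent inside the family. A binned summary (median occupancy and
#' a 95% bootstrap-free quantile band per CID bin) is attached.
#'
#' @param imd inter-mouse distance series (mm).
#' @param occupancy logical occupancy series (same length).
#' @param window window length in frames.
#' @param cid_breaks bin edges for the summary (mm).
#' @return list of class `soseq_rolling_relation`: `windows` (tibble `cid`,
#'   `occupancy`), `summary` (per-bin medians and 2.5/97.5% quantiles).
#' @export
rolling_relation <- function(imd, occupancy, window = 30L,
                             cid_breaks = seq(-450, 450, by = 50)) {
  n <- length(imd)
  if (length(occupancy) != n) abort("series must have equal length")
  if (window > n) abort("window longer than recording")
  idx <- seq_len(n - window + 1L)
  cid <- imd[idx + window - 1L] - imd[idx]
  cs <- cumsum(c(0, occupancy))
  occ <- (cs[idx + window] - cs[idx]) / window
  w <- tibble(cid = cid, occupancy = occ)
  smry <- w %>%
    mutate(bin = cut(.data$cid, cid_breaks)) %>%
    filter(!is.na(.data$bin)) %>%
    group_by(.data$bin) %>%
    summarise(n = dplyr::n(), median_occ = median(.data$occupancy),
              lo = quantile(.data$occupancy, 0.025),
              hi = quantile(.data$occupancy, 0.975), .groups = "drop")
  structure(list(windows = w, summary = smry, window = window),
            class = "soseq_rolling_relation")
}

#' @export
tidy.soseq_rolling_relation <- function(x, ...) x$summary
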