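#' Kullback-Leibler divergence between two discrete distributions
#'
#' `sum(p * log(p/q))` in nats, with `0 * log(0/.) = 0`. The reference `q`
#' is smoothed with a pseudocount per category (default `1e-6`) and
#' renormalized so its support covers that of `p`; `p` is renormalized if
#' it does not sum to 1.
#'
#' @param p,q non-negative numeric vectors of equal length.
#' @param pseudocount added to every category of `q` before renormalizing;
#'   0 disables smoothing (then a `p`-supported zero in `q` is an error).
#' @return divergence in nats (non-negative up to floating point).
#' @export
dkl <- function(p, q, pseudocount = 1e-6) {
  if (length(p) != length(q)) abort("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) abort("distributions must be non-negative")
  if (sum(p) == 0) abort("p has no mass")
  p <- p / sum(p)
  q <- q + pseudocount
  if (sum(q) == 0) abort("q has no mass")
  q <- q / sum(q)
  nz <- p > 0
  if (any(q[nz] == 0)) {
    abort("support of q does not cover p; use a positive pseudocount")
  }
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Frame-wise syllable distribution of a set of sequences
#'
#' @param sequences sequence tibble.
#' @param n_syllables vocabulary size.
#' @return probability vector over `0..n_syllables-1` (missing frames
#'   excluded).
#' @export
label_distribution <- function(sequences, n_syllables) {
  counts <- numeric(n_syllables)
  for (lab in sequences$labels) {
    lab <- lab[lab >= 0L]
    counts <- counts + tabulate(lab + 1L, nbins = n_syllables)
  }
  if (sum(counts) == 0) abort("no assigned frames")
  counts / sum(counts)
}

#' Bout-order shuffle control
#'
#' Permutes the order of a sequence's bouts uniformly at random while
#' preserving every bout's duration, then re-flattens to frames; the frame
#' count and per-syllable frame totals are unchanged. Used as the
#' randomized control that destroys event alignment while keeping
#' composition.
#'
#' @param seq_row one-row sequence tibble.
#' @param seed integer seed.
#' @return one-row sequence tibble with shuffled labels.
#' @export
shuffle_control <- function(seq_row, seed) {
  labels <- seq_row$labels[[1]]
  iv <- rle_intervals(labels)
  if (nrow(iv) < 2L) return(seq_row)
  ord <- with_seed(seed, sample.int(nrow(iv)))
  iv <- iv[ord, ]
  out <- rep.int(iv$syllable, iv$end - iv$start)
  seq_row$labels <- list(as.integer(out))
  seq_row
}

# qualifying contact bouts: no same-type bout intersecting the pre-window,
# and a full pre-window inside the recording
qualifying_bouts <- function(annotations, contact_type, pre_window) {
  ann <- annotations[annotations$contact_type == contact_type, ]
  keep <- map_lgl(seq_len(nrow(ann)), function(i) {
    s <- ann$start[i]
    if (s < pre_window) return(FALSE)
    same <- ann[-i, ]
    same <- same[same$recording_id == ann$recording_id[i], ]
    !any(same$end > s - pre_window & same$start < s)
  })
  ann[keep, ]
}

# offsets x samples label matrix for a set of aligned starts
aligned_label_matrix <- function(labels, starts, offsets) {
  idx <- outer(starts, offsets, `+`) + 1L       # 1-based frame index
  bad <- idx < 1L | idx > length(labels)
  idx[bad] <- 1L
  m <- matrix(labels[idx], nrow = length(starts))
  m[bad] <- NA_integer_
  m[!is.na(m) & m < 0L] <- NA_integer_
  m
}

# shared binning + bootstrap significance machinery; `samples` is a
# samples x offsets integer category matrix, categories 0..K-1.
# The null resamples whole bin-width segments of baseline-window rows (not
# single frames): labels within a segment come from the same aligned window
# and are strongly autocorrelated through the bout structure, so a
# frame-level bootstrap would badly understate the sampling variance of the
# per-bin divergence. One null sample of 'm' segments matches a bin
# supported by 'm' windows; nulls are shared across bins of equal support.
dkl_timecourse_engine <- function(samples, offsets, K, q, pre_window,
                                  bin_width, pseudocount, alpha,
                                  min_support, n_boot, seed) {
  bin <- (offsets + pre_window) %/% bin_width
  bins <- sort(unique(bin))
  baseline_bins <- bins[bins * bin_width - pre_window < 0]
  seg_labels <- list()
  for (b in baseline_bins) {
    cols <- which(bin == b)
    for (r in seq_len(nrow(samples))) {
      v <- samples[r, cols]
      v <- v[!is.na(v)]
      if (length(v)) seg_labels[[length(seg_labels) + 1L]] <- as.integer(v)
    }
  }
  if (length(seg_labels) < 2L) abort("empty baseline pool")
  obs <- lapply(bins, function(b) {
    v <- as.integer(samples[, bin == b, drop = FALSE])
    v[!is.na(v)]
  })
  n_bouts <- vapply(bins, function(b) {
    sum(rowSums(!is.na(samples[, bin == b, drop = FALSE])) > 0)
  }, integer(1))
  res <- with_seed(seed, {
    tested <- n_bouts >= min_support & lengths(obs) > 0L
    nulls <- lapply(sort(unique(n_bouts[tested])), function(m) {
      vapply(seq_len(n_boot), function(i) {
        v <- unlist(seg_labels[sample.int(length(seg_labels), m, replace = TRUE)],
                    use.names = FALSE)
        dkl(tabulate(v + 1L, nbins = K) / length(v), q, pseudocount)
      }, numeric(1))
    })
    names(nulls) <- sort(unique(n_bouts[tested]))
    lapply(seq_along(bins), function(k) {
      v <- obs[[k]]
      if (!tested[k]) {
        return(tibble(dkl = NA_real_, p_raw = NA_real_, z = NA_real_,
                      n = length(v)))
      }
      p_emp <- tabulate(v + 1L, nbins = K) / length(v)
      d_obs <- dkl(p_emp, q, pseudocount)
      null <- nulls[[as.character(n_bouts[k])]]
      tibble(dkl = d_obs,
             p_raw = (1 + sum(null >= d_obs)) / (n_boot + 1),
             z = if (sd(null) > 0) (d_obs - mean(null)) / sd(null) else NA_real_,
             n = length(v))
    })
  })
  out <- bind_rows(res) %>%
    mutate(bin = bins,
           offset_lo = bins * bin_width - pre_window,
           offset_mid = .data$offset_lo + (bin_width - 1) / 2,
           n_bouts = n_bouts, .before = 1L)
  out$p_adjusted <- NA_real_
  tested <- !is.na(out$p_raw)
  out$p_adjusted[tested] <- adjust_p(out$p_raw[tested], "benjamini_hochberg")
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Contact-aligned syllable-composition divergence time-course
#'
#' For every qualifying contact bout (clean pre-contact window, see
#' [pool_annotations()]) both animals of the recording contribute their
#' frame-wise syllable labels at each offset relative to bout onset. Within
#' each offset bin the empirical label distribution is compared with the
#' overall dyadic-context distribution by Kullback-Leibler divergence
#' (nats). Per-bin significance comes from a bootstrap-over-bouts null
#' drawn from the pooled baseline-window labels at matched sample size,
#' Benjamini-Hochberg corrected across bins; z-scores against the
#' bootstrap null are also reported.
#'
#' @param sequences dyadic sequence tibble.
#' @param annotations pooled annotation tibble.
#' @param n_syllables vocabulary size.
#' @param contact_type `"active"` or `"passive"`.
#' @param pre_window baseline/control window before onset, frames (125 =
#'   5 s at 25 Hz).
#' @param post_window frames after onset to follow.
#' @param bin_width offset bin width in frames.
#' @param pseudocount smoothing of the reference distribution.
#' @param alpha significance level.
#' @param min_support minimum contributing bouts per bin; smaller bins are
#'   masked, not tested.
#' @param n_boot bootstrap replicates per support size (1000 by default: the
#'   discrete p-value floor 1/(n_boot+1) must stay well below alpha divided
#'   by the number of tested bins for the Benjamini-Hochberg correction to
#'   be able to reject).
#' @param seed seed for the bootstrap.
#' @param reference optional reference distribution; defaults to the pooled
#'   distribution of `sequences`.
#' @return object of class `soseq_dkl_timecourse`; `tidy()` returns the
#'   per-bin tibble.
#' @export
aligned_timecourse <- function(sequences, annotations, n_syllables,
                               contact_type = "active", pre_window = 125L,
                               post_window = 250L, bin_width = 5L,
                               pseudocount = 1e-6, alpha = 0.05,
                               min_support = 5L, n_boot = 1000L, seed = 1L,
                               reference = NULL) {
  q <- reference %||% label_distribution(sequences, n_syllables)
  ann <- qualifying_bouts(annotations, contact_type, pre_window)
  if (nrow(ann) == 0L) abort("no qualifying contact bouts")
  offsets <- seq.int(-pre_window, post_window - 1L)
  mats <- list()
  for (r in unique(ann$recording_id)) {
    starts <- ann$start[ann$recording_id == r]
    rec_seqs <- sequences[sequences$recording_id == r, ]
    for (i in seq_len(nrow(rec_seqs))) {
      mats[[length(mats) + 1L]] <-
        aligned_label_matrix(rec_seqs$labels[[i]], starts, offsets)
    }
  }
  if (!length(mats)) abort("no sequences match the annotated recordings")
  samples <- do.call(rbind, mats)
  course <- dkl_timecourse_engine(samples, offsets, n_syllables, q,
                                  pre_window, bin_width, pseudocount,
                                  alpha, min_support, n_boot, seed)
  structure(list(course = course, contact_type = contact_type,
                 n_qualifying = nrow(ann), units = "nats", joint = FALSE,
                 baseline = c(-pre_window, 0L), alpha = alpha),
            class = "soseq_dkl_timecourse")
}

#' Joint two-mouse composition divergence time-course
#'
#' As [aligned_timecourse()] but the categories are ordered syllable pairs
#' of the two animals in each recording (n^2 cells, pseudocount-smoothed),
#' so coordinated composition changes are detected even when the marginals
#' move little. A warning is emitted when pair-category occupancy is
#' sparse.
#'
#' @inheritParams aligned_timecourse
#' @return object of class `soseq_dkl_timecourse`.
#' @export
joint_timecourse <- function(sequences, annotations, n_syllables,
                             contact_type = "active", pre_window = 125L,
                             post_window = 250L, bin_width = 5L,
                             pseudocount = 1e-6, alpha = 0.05,
                             min_support = 5L, n_boot = 1000L, seed = 1L) {
  ann <- qualifying_bouts(annotations, contact_type, pre_window)
  if (nrow(ann) == 0L) abort("no qualifying contact bouts")
  offsets <- seq.int(-pre_window, post_window - 1L)
  K <- n_syllables^2L
  # overall joint distribution pooled over recordings
  joint_counts <- numeric(K)
  pair_codes <- function(l1, l2) {
    ok <- l1 >= 0L & l2 >= 0L
    (l1[ok] * n_syllables + l2[ok])
  }
  mats <- list()
  for (r in unique(sequences$recording_id)) {
    rec_seqs <- sequences[sequences$recording_id == r, ]
    if (nrow(rec_seqs) != 2L) next
    l1 <- rec_seqs$labels[[1]]; l2 <- rec_seqs$labels[[2]]
    if (length(l1) != length(l2)) abort("paired sequences must have equal length")
    joint_counts <- joint_counts +
      tabulate(pair_codes(l1, l2) + 1L, nbins = K)
    starts <- ann$start[ann$recording_id == r]
    if (!length(starts)) next
    m1 <- aligned_label_matrix(l1, starts, offsets)
    m2 <- aligned_label_matrix(l2, starts, offsets)
    m <- m1 * n_syllables + m2
    m[is.na(m1) | is.na(m2)] <- NA_integer_
    mats[[length(mats) + 1L]] <- m
  }
  if (!length(mats)) abort("no paired sequences match the annotated recordings")
  if (sum(joint_counts) == 0) abort("no joint frames")
  q <- joint_counts / sum(joint_counts)
  if (mean(joint_counts > 0) < 0.25) {
    warn("joint pair-category occupancy is sparse; divergences rely on smoothing")
  }
  samples <- do.call(rbind, mats)
  course <- dkl_timecourse_engine(samples, offsets, K, q, pre_window,
                                  bin_width, pseudocount, alpha,
                                  min_support, n_boot, seed)
  structure(list(course = course, contact_type = contact_type,
                 n_qualifying = nrow(ann), units = "nats", joint = TRUE,
                 baseline = c(-pre_window, 0L), alpha = alpha),
            class = "soseq_dkl_timecourse")
}

#' @export
tidy.soseq_dkl_timecourse <- function(x, ...) x$course

#' @export
glance.soseq_dkl_timecourse <- function(x, ...) {
  post <- x$course[x$course$offset_lo >= 0 & !is.na(x$course$p_raw), ]
  tibble(contact_type = x$contact_type, joint = x$joint,
         n_qualifying = x$n_qualifying,
         n_bins_tested = sum(!is.na(x$course$p_raw)),
         n_bins_significant = sum(x$course$significant),
         n_postonset_significant = sum(post$significant),
         peak_dkl = max(x$course$dkl, na.rm = TRUE))
}

#' @export
print.soseq_dkl_timecourse <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<%s D_KL time-course (%s): %d qualifying bouts, %d/%d bins significant (%d post-onset)>\n",
              if (x$joint) "joint" else "single-mouse", x$contact_type,
              g$n_qualifying, g$n_bins_significant, g$n_bins_tested,
              g$n_postonset_significant))
  invisible(x)
}
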