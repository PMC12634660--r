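# Planted-effect recovery and type-I-control batteries over replicate
# seeds of the synthetic generator. These drive the package's validation:
# the planted configuration must be recovered and the null configuration
# must stay null.

#' Planted-effect recovery metrics for one synthetic experiment
#'
#' Simulates one experiment from `cfg`, runs the recovery analyses, and
#' scores them against the generator's ground truth:
#' \itemize{
#'   \item `sensitivity`: fraction of planted DM ids flagged by
#'     [compare_contexts()].
#'   \item `false_positives`: flagged ids that are neither planted nor
#'     recorded network spillover (`ground_truth$spillover_ids` — non-planted
#'     ids whose analytically expected onset shift exceeds 5%).
#'   \item `centrality_frac`: fraction of planted ids flagged by
#'     [centrality_context_test()].
#'   \item `dkl_post_sig` / `dkl_shuffle_sig`: significant post-onset bins in
#'     the active-contact divergence time-course, on the real and on
#'     bout-shuffled sequences ([shuffle_control()]).
#'   \item `approach_frac` / `leave_frac`: completed planted episodes whose
#'     kinematic point is classified as its own type.
#'   \item `occ_cid_low` / `occ_cid_high`: mean approach-family occupancy of
#'     rolling windows with change-in-distance below / above -200 mm.
#' }
#'
#' @param seed root seed for the experiment (and derived analysis seeds).
#' @param cfg a [synthetic_config()]; its `seed` is overridden by `seed`.
#' @return one-row tibble of metrics.
#' @export
recover_planted <- function(seed, cfg = synthetic_config()) {
  cfg$seed <- as.integer(seed)
  exp <- simulate_experiment(cfg)
  gt <- exp$ground_truth
  n_syl <- cfg$n_syllables
  bouts <- extract_bouts(exp$sequences)
  mod <- compare_contexts(syllable_proportions(bouts, n_syl))
  truly_modulated <- union(gt$planted_dm, gt$spillover_ids)

  cent <- centrality_table(transition_networks(bouts, n_syl))
  ct <- centrality_context_test(cent)

  dseq <- exp$sequences[exp$sequences$context == "dyadic", ]
  ann <- pool_annotations(exp$annotations)
  aseeds <- derive_seeds(seed, c("dkl", "shuffle"))
  tc <- aligned_timecourse(dseq, ann, n_syl, "active", seed = aseeds[["dkl"]])
  shuffle_seeds <- derive_seeds(aseeds[["shuffle"]],
                                paste(dseq$recording_id, dseq$animal_id))
  shuf <- bind_rows(lapply(seq_len(nrow(dseq)), function(i) {
    shuffle_control(dseq[i, ], shuffle_seeds[[i]])
  }))
  tcs <- aligned_timecourse(shuf, ann, n_syl, "active", seed = aseeds[["dkl"]])
  post <- function(x) x$course[x$course$offset_lo >= 0 & !is.na(x$course$p_raw), ]

  eps <- gt$episodes
  imd_list <- list()
  for (r in unique(exp$tracks$recording_id[duplicated(exp$tracks$recording_id)])) {
    imd_list[[r]] <- imd_series(exp$tracks[exp$tracks$recording_id == r, ])
  }
  ep_frac <- function(type) {
    e <- eps[eps$type == type & eps$completed, ]
    if (nrow(e) == 0L) return(NA_real_)
    x <- vapply(seq_len(nrow(e)), function(i) {
      imd_list[[e$recording_id[i]]][e$start[i] + 1L]
    }, numeric(1))
    y <- vapply(seq_len(nrow(e)), function(i) {
      s <- imd_list[[e$recording_id[i]]]
      s[min(e$end[i], length(s))] - s[e$start[i] + 1L]
    }, numeric(1))
    cls <- suppressMessages(classify_kinematics(x, y, cfg$contact_mm))
    mean(cls$class == type)
  }

  sy <- extract_syntaxes(bouts)
  syd <- sy[sy$context == "dyadic", ]
  occ_low <- occ_high <- numeric(0)
  for (r in names(imd_list)) {
    occ <- family_occupancy(syd[syd$recording_id == r, ],
                            cfg$family_syntaxes$approach,
                            length(imd_list[[r]]))
    rr <- rolling_relation(imd_list[[r]], occ)
    w <- rr$windows
    occ_low <- c(occ_low, mean(w$occupancy[w$cid < -200]))
    occ_high <- c(occ_high, mean(w$occupancy[w$cid >= -200]))
  }

  tibble(
    seed = as.integer(seed),
    sensitivity = mean(gt$planted_dm %in% mod$dm),
    false_positives = length(setdiff(mod$dm, truly_modulated)),
    n_spillover = length(gt$spillover_ids),
    centrality_frac = mean(gt$planted_dm %in% ct$syllable[ct$significant]),
    dkl_post_sig = sum(post(tc)$significant),
    dkl_post_tested = nrow(post(tc)),
    dkl_shuffle_sig = sum(post(tcs)$significant),
    approach_frac = ep_frac("approach"),
    leave_frac = ep_frac("leave"),
    occ_cid_low = mean(occ_low, na.rm = TRUE),
    occ_cid_high = mean(occ_high, na.rm = TRUE)
  )
}

#' Type-I-control metrics for one null synthetic experiment
#'
#' Simulates one experiment from a configuration with all planted effects
#' switched off and records the quantities that must stay at their nominal
#' false-positive level: the DM count from [compare_contexts()], the
#' significant-edge count from [transition_modulation()], and the fraction
#' of significant bins in the active-contact divergence time-course.
#'
#' @param seed root seed.
#' @param cfg a null configuration (see [null_synthetic_config()]).
#' @return one-row tibble `seed`, `dm_false_positives`, `dm_fp_fraction`,
#'   `n_significant_edges`, `edge_fraction`, `dkl_sig_fraction`.
#' @export
null_metrics <- function(seed, cfg = null_synthetic_config()) {
  cfg$seed <- as.integer(seed)
  exp <- simulate_experiment(cfg)
  n_syl <- cfg$n_syllables
  bouts <- extract_bouts(exp$sequences)
  mod <- compare_contexts(syllable_proportions(bouts, n_syl))
  em <- transition_modulation(transition_networks(bouts, n_syl))
  dseq <- exp$sequences[exp$sequences$context == "dyadic", ]
  ann <- pool_annotations(exp$annotations)
  aseeds <- derive_seeds(seed, "dkl")
  tc <- aligned_timecourse(dseq, ann, n_syl, "active", seed = aseeds[["dkl"]])
  tested <- !is.na(tc$course$p_raw)
  tibble(
    seed = as.integer(seed),
    dm_false_positives = length(mod$dm),
    dm_fp_fraction = length(mod$dm) / n_syl,
    n_significant_edges = sum(em$edges$significant),
    edge_fraction = sum(em$edges$significant) / nrow(em$edges),
    dkl_sig_fraction = sum(tc$course$significant) / sum(tested)
  )
}

#' Run a recovery or null battery over replicate seeds
#'
#' @param seeds integer vector of root seeds.
#' @param cfg configuration passed to each replicate.
#' @return tibble with one row per seed (see [recover_planted()] /
#'   [null_metrics()]).
#' @export
planted_recovery_battery <- function(seeds, cfg = synthetic_config()) {
  bind_rows(lapply(seeds, recover_planted, cfg = cfg))
}

#' @rdname planted_recovery_battery
#' @export
null_control_battery <- function(seeds, cfg = null_synthetic_config()) {
  bind_rows(lapply(seeds, null_metrics, cfg = cfg))
}
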