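#' Synthetic experiment configuration
#'
#' Parameters of the synthetic-experiment generator. The generator emulates
#' the statistical structure the downstream analyses assume: a 32-syllable
#' vocabulary with a geometric bout-duration distribution (median 10 frames
#' at 25 Hz), 20-minute recordings, a 453 mm square arena with corner
#' preference, a planted subset of dyadic-modulated (DM) syllables whose
#' usage and incoming transition mass increase in dyadic context, scored
#' contact bouts arising when the mice are proximal, and approach/leave
#' episodes coupled to two reference syntax families.
#'
#' `dm_effect` and `centrality_boost` act multiplicatively on the planted
#' syllables' columns (incoming transition probability mass) of the dyadic
#' base matrix before row renormalization; usage and centrality modulation
#' are therefore coupled by construction. Setting both to 1 and the contact
#' planting probabilities to 0 yields a null experiment with no
#' context effect.
#'
#' @param n_syllables vocabulary size.
#' @param n_animals_per_context animals per context (dyadic animals are
#'   paired, so this must be even).
#' @param duration_s recording length in seconds.
#' @param frame_rate frames per second.
#' @param planted_dm integer ids of the planted dyadic-modulated syllables.
#' @param dm_effect multiplicative usage change of planted syllables in
#'   dyadic context.
#' @param centrality_boost multiplicative increase of incoming transition
#'   mass to planted ids in dyadic context.
#' @param duration_median_frames target median bout duration (frames).
#' @param arena_mm square arena side (mm).
#' @param contact_mm proximity threshold defining contact (mm).
#' @param family_syntaxes list with reference triples `approach` and `leave`
#'   injected during the corresponding episodes.
#' @param animal_concentration Dirichlet concentration (per row) of
#'   per-animal transition matrices around the context base; larger means
#'   less between-animal variability.
#' @param n_approach,n_leave planted episodes per dyadic recording.
#' @param active_prob probability a generated contact run is scored active
#'   (else passive).
#' @param contact_bias_ids syllables favoured during active contact.
#' @param contact_bias_strength weight multiplier on `contact_bias_ids` when
#'   redrawing in-contact bout labels.
#' @param contact_syllable_prob probability each bout overlapping an active
#'   contact run is redrawn from the biased composition (0 disables the
#'   planted composition shift).
#' @param contact_syntax triple planted at active contact onsets.
#' @param contact_syntax_prob probability the triple is planted at a given
#'   active run onset (0 disables).
#' @param dm_speed_factor locomotor speed multiplier while a planted DM
#'   syllable is active (DM syllables emulate stationary behaviors).
#' @param speed_mm_s baseline locomotor speed scale (mm/s).
#' @param approach_speed_mm_s steering speed during approach/leave episodes.
#' @param corner_pref probability a newly drawn movement goal is a corner
#'   rather than a uniform interior point.
#' @param seed root seed; all randomness flows from it through named
#'   substreams.
#'
#' @return a list of class `soseq_synth_config`.
#' @export
synthetic_config <- function(n_syllables = 32L,
                             n_animals_per_context = 20L,
                             duration_s = 1200,
                             frame_rate = 25,
                             planted_dm = c(7L, 10L, 12L, 13L, 18L, 23L, 28L, 30L),
                             dm_effect = 1.6,
                             centrality_boost = 1.5,
                             duration_median_frames = 10,
                             arena_mm = 453,
                             contact_mm = 100,
                             family_syntaxes = list(approach = c(9L, 0L, 5L),
                                                    leave = c(11L, 2L, 8L)),
                             animal_concentration = 200,
                             n_approach = 6L,
                             n_leave = 6L,
                             active_prob = 0.5,
                             contact_bias_ids = c(7L, 10L, 12L, 13L),
                             contact_bias_strength = 6,
                             contact_syllable_prob = 0.5,
                             contact_syntax = c(7L, 10L, 12L),
                             contact_syntax_prob = 0.7,
                             dm_speed_factor = 0.25,
                             speed_mm_s = 120,
                             approach_speed_mm_s = 260,
                             corner_pref = 0.7,
                             seed = 1L) {
  if (n_syllables < 3L) abort("n_syllables must be at least 3")
  planted_dm <- as.integer(planted_dm)
  if (any(planted_dm < 0L | planted_dm >= n_syllables)) {
    abort("planted_dm ids must lie in 0..n_syllables-1")
  }
  if (dm_effect <= 0 || centrality_boost <= 0) abort("effects must be positive")
  contact_bias_ids <- as.integer(contact_bias_ids)
  contact_syntax <- as.integer(contact_syntax)
  for (ids in list(contact_bias_ids, contact_syntax,
                   unlist(family_syntaxes))) {
    if (any(ids < 0L | ids >= n_syllables)) {
      abort("all planted syllable ids must lie in 0..n_syllables-1")
    }
  }
  if (duration_median_frames < 1) abort("duration_median_frames must be >= 1")
  if (n_animals_per_context %% 2L != 0L) {
    abort("n_animals_per_context must be even (dyadic animals are paired)")
  }
  cfg <- as.list(environment())
  structure(cfg, class = c("soseq_synth_config", "list"))
}

#' @rdname synthetic_config
#' @param ... overrides forwarded to [synthetic_config()].
#' @details `null_synthetic_config()` is a convenience preset with all
#'   planted effects switched off (`dm_effect = 1`, `centrality_boost = 1`,
#'   no contact composition planting), used for type-I-error control runs.
#' @export
null_synthetic_config <- function(...) {
  synthetic_config(dm_effect = 1, centrality_boost = 1,
                   contact_syllable_prob = 0, contact_syntax_prob = 0, ...)
}

# Dirichlet draw over the off-diagonal entries of one row.
rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[] <- 1
  g / sum(g)
}

zero_diag_rownorm <- function(M) {
  diag(M) <- 0
  rs <- rowSums(M)
  rs[rs == 0] <- 1
  M / rs
}

# Mass-preserving column modulation of the planted syllables.
#
# The first half of the planted ids (rounding up) is boosted by `m`, the
# second half suppressed by `1/m`; within every row the planted block is
# then rescaled so its total probability mass matches the unmodulated row.
# Non-planted transition probabilities are therefore exactly unchanged and
# rows still sum to 1, so only the planted syllables are truly modulated.
plant_dm_columns <- function(base, planted_dm, m) {
  k <- length(planted_dm)
  if (k == 0L || m == 1) return(base)
  cols <- planted_dm + 1L
  w <- rep(c(m, 1 / m), c(ceiling(k / 2), floor(k / 2)))
  for (i in seq_len(nrow(base))) {
    p <- base[i, cols]
    tot <- sum(p)
    if (tot == 0) next
    s <- p * w
    base[i, cols] <- s * (tot / sum(s))
  }
  base
}

#' Generate context base and per-animal transition matrices
#'
#' The base matrix is drawn once from a symmetric Dirichlet over the
#' off-diagonal entries of each row (shared by both contexts under the same
#' root seed). For the dyadic context the planted syllables are modulated
#' mass-preservingly: the first half of the planted ids is boosted by
#' `dm_effect * centrality_boost`, the second half suppressed by its
#' reciprocal, and the planted block of every row rescaled to its original
#' total mass — so non-planted transition probabilities are exactly equal
#' across contexts and only the planted set is modulated. Per-animal
#' matrices are drawn row-wise from a Dirichlet
#' centred on the context base with concentration
#' `animal_concentration`. All matrices have an exactly zero diagonal and
#' rows summing to 1.
#'
#' @param cfg a [synthetic_config()].
#' @param context `"solitary"` or `"dyadic"`.
#' @param n_animals number of per-animal matrices to draw.
#' @return list with `base` (matrix) and `animals` (list of matrices).
#' @export
generate_transition_matrices <- function(cfg, context = c("solitary", "dyadic"),
                                         n_animals = cfg$n_animals_per_context) {
  context <- match.arg(context)
  n <- cfg$n_syllables
  seeds <- derive_seeds(cfg$seed, c("base", "animals_solitary", "animals_dyadic"))
  base <- with_seed(seeds[["base"]], {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      M[i, -i] <- rdirichlet_row(rep(1, n - 1L))
    }
    M
  })
  if (context == "dyadic") {
    base <- plant_dm_columns(base, cfg$planted_dm,
                             cfg$dm_effect * cfg$centrality_boost)
  }
  animal_seed <- seeds[[paste0("animals_", context)]]
  animals <- with_seed(animal_seed, {
    lapply(seq_len(n_animals), function(a) {
      M <- matrix(0, n, n)
      for (i in seq_len(n)) {
        M[i, -i] <- rdirichlet_row(cfg$animal_concentration * base[i, -i])
      }
      M
    })
  })
  list(base = base, animals = animals)
}

# geometric success probability giving median `m` for durations 1 + Geom(p)
geom_prob_for_median <- function(m) 1 - 2^(-1 / (m - 0.5))

#' Generate one semi-Markov syllable sequence
#'
#' Bout labels follow the supplied zero-diagonal row-stochastic transition
#' matrix; bout durations are i.i.d. `1 + Geometric(p)` with `p` calibrated
#' so the median duration is `cfg$duration_median_frames`. The sequence is
#' truncated to `duration_s * frame_rate` frames. Identical seeds give
#' identical output.
#'
#' @param P zero-diagonal row-stochastic matrix.
#' @param cfg a [synthetic_config()] (duration, frame rate, median bout
#'   length are read from it).
#' @param seed integer seed for this sequence.
#' @return integer vector of frame-wise labels (0-based syllable ids).
#' @export
generate_sequence <- function(P, cfg, seed) {
  n <- nrow(P)
  if (!isTRUE(all.equal(rowSums(P), rep(1, n), tolerance = 1e-8)) ||
      any(P < 0) || any(abs(diag(P)) > 1e-12)) {
    abort("P must be zero-diagonal and row-stochastic")
  }
  n_frames <- round(cfg$duration_s * cfg$frame_rate)
  p_geom <- geom_prob_for_median(cfg$duration_median_frames)
  with_seed(seed, {
    cum <- t(apply(P, 1L, cumsum))
    n_bouts_guess <- ceiling(1.3 * n_frames * p_geom) + 50L
    states <- integer(n_bouts_guess)
    durs <- 1L + rgeom(n_bouts_guess, p_geom)
    u <- runif(n_bouts_guess)
    s <- sample.int(n, 1L)
    total <- 0L
    i <- 0L
    while (total < n_frames) {
      i <- i + 1L
      if (i > length(states)) {
        states <- c(states, integer(length(states)))
        durs <- c(durs, 1L + rgeom(length(durs), p_geom))
        u <- c(u, runif(length(u)))
      }
      states[i] <- s
      total <- total + durs[i]
      s <- findInterval(u[i], cum[s, ]) + 1L
      if (s > n) s <- n
    }
    labels <- rep.int(states[seq_len(i)], durs[seq_len(i)])[seq_len(n_frames)]
    as.integer(labels - 1L)
  })
}

# Simulate correlated random walks for a set of animals simultaneously.
# `partner` is the (1-based) index of each animal's arena partner, NA for
# solitary animals. `episodes` is a tibble (animal, type [approach|leave],
# t0, deadline) of planted steering episodes. `speed_mult` is an
# n_frames x n_animals matrix of per-frame speed multipliers (syllable
# coupling). Returns positions and the realized episode log.
sim_tracks <- function(n_frames, n_anim, arena, dt, partner, episodes,
                       speed_mult, cfg, seed) {
  with_seed(seed, {
    corners <- matrix(c(0, 0, arena, 0, 0, arena, arena, arena),
                      ncol = 2L, byrow = TRUE)
    margin <- 15
    pos <- cbind(runif(n_anim, margin, arena - margin),
                 runif(n_anim, margin, arena - margin))
    vel <- matrix(0, n_anim, 2L)
    goal <- pos
    rho <- 0.85
    sigma <- 10                     # velocity noise, mm/s per step
    X <- matrix(NA_real_, n_frames, n_anim)
    Y <- matrix(NA_real_, n_frames, n_anim)

    # per-animal episode schedule as padded matrices
    n_ep <- if (nrow(episodes)) max(table(factor(episodes$animal, levels = seq_len(n_anim)))) else 0L
    ep_t0 <- matrix(Inf, max(n_ep, 1L), n_anim)
    ep_dl <- matrix(Inf, max(n_ep, 1L), n_anim)
    ep_ty <- matrix(0L, max(n_ep, 1L), n_anim)   # 1 approach, 2 leave
    if (nrow(episodes)) {
      episodes <- arrange(episodes, .data$animal, .data$t0)
      for (a in unique(episodes$animal)) {
        e <- episodes[episodes$animal == a, ]
        ep_t0[seq_len(nrow(e)), a] <- e$t0
        ep_dl[seq_len(nrow(e)), a] <- e$deadline
        ep_ty[seq_len(nrow(e)), a] <- ifelse(e$type == "approach", 1L, 2L)
      }
    }
    ptr <- rep(1L, n_anim)
    active <- rep(FALSE, n_anim)
    act_start <- rep(NA_integer_, n_anim)
    act_imd0 <- rep(NA_real_, n_anim)
    log_animal <- integer(0); log_type <- integer(0)
    log_start <- integer(0); log_end <- integer(0)
    log_imd0 <- numeric(0); log_imd1 <- numeric(0); log_done <- logical(0)

    far_arm <- 250; done_app <- 80; done_leave <- cfg$contact_mm + 100
    has_partner <- !is.na(partner)
    pidx <- ifelse(has_partner, partner, seq_len(n_anim))
    noise <- matrix(rnorm(n_frames * n_anim * 2L, 0, sigma), n_frames)
    gswitch <- matrix(runif(n_frames * n_anim), n_frames)
    gcorner <- matrix(runif(n_frames * n_anim), n_frames)

    aidx <- seq_len(n_anim)
    for (f in seq_len(n_frames)) {
      dvec <- pos[pidx, , drop = FALSE] - pos
      imd <- sqrt(rowSums(dvec^2))

      if (n_ep > 0L) {
        k <- pmin(ptr, n_ep)
        cur <- cbind(k, aidx)
        t0 <- ep_t0[cur]; dl <- ep_dl[cur]; ty <- ep_ty[cur]
        waiting <- !active & ptr <= n_ep & f >= t0
        arm <- waiting & ((ty == 1L & imd > far_arm) | (ty == 2L & imd < done_app))
        if (any(arm)) {
          active[arm] <- TRUE
          act_start[arm] <- f
          act_imd0[arm] <- imd[arm]
        }
        skipped <- waiting & !arm & f >= dl
        if (any(skipped)) ptr[skipped] <- ptr[skipped] + 1L
        fin <- active & ((ty == 1L & imd < done_app) |
                         (ty == 2L & imd > done_leave) | f >= dl)
        if (any(fin)) {
          for (a in which(fin)) {
            log_animal <- c(log_animal, a)
            log_type <- c(log_type, ty[a])
            log_start <- c(log_start, act_start[a])
            log_end <- c(log_end, f)
            log_imd0 <- c(log_imd0, act_imd0[a])
            log_imd1 <- c(log_imd1, imd[a])
            log_done <- c(log_done, f < dl[a])
          }
          active[fin] <- FALSE
          ptr[fin] <- ptr[fin] + 1L
        }
      }

      # desired direction: goal-seeking, overridden by episode steering
      dirg <- goal - pos
      ng <- sqrt(rowSums(dirg^2)); ng[ng < 1e-9] <- 1
      des_dir <- dirg / ng
      des_speed <- cfg$speed_mm_s * speed_mult[f, ]
      if (any(active)) {
        k <- pmin(ptr, max(n_ep, 1L))
        ty <- ep_ty[cbind(k, aidx)]
        steer <- dvec / pmax(imd, 1e-9)
        app <- active & ty == 1L
        lev <- active & ty == 2L
        des_dir[app, ] <- steer[app, , drop = FALSE]
        des_dir[lev, ] <- -steer[lev, , drop = FALSE]
        des_speed[active] <- cfg$approach_speed_mm_s
      }

      vel <- rho * vel + (1 - rho) * des_speed * des_dir +
        cbind(noise[f, aidx], noise[f, n_anim + aidx])
      pos <- pos + vel * dt
      # clip to walls, kill outward velocity component
      for (d in 1:2) {
        lo <- pos[, d] < margin; hi <- pos[, d] > arena - margin
        pos[lo, d] <- margin; pos[hi, d] <- arena - margin
        vel[lo | hi, d] <- 0
      }
      X[f, ] <- pos[, 1]; Y[f, ] <- pos[, 2]

      # goal resampling: reached or random switch
      reached <- rowSums((goal - pos)^2) < 30^2
      switch_now <- reached | gswitch[f, ] < 0.004
      if (any(switch_now)) {
        idx <- which(switch_now)
        corner_pick <- gcorner[f, idx] < cfg$corner_pref
        ci <- sample.int(4L, length(idx), replace = TRUE)
        newg <- cbind(runif(length(idx), margin, arena - margin),
                      runif(length(idx), margin, arena - margin))
        newg[corner_pick, ] <- corners[ci[corner_pick], , drop = FALSE] +
          matrix(runif(2L * sum(corner_pick), -40, 40), ncol = 2L)
        newg[, 1] <- pmin(pmax(newg[, 1], margin), arena - margin)
        newg[, 2] <- pmin(pmax(newg[, 2], margin), arena - margin)
        goal[idx, ] <- newg
      }
    }
    ep_log <- tibble(
      animal = log_animal,
      type = c("approach", "leave")[log_type],
      start = log_start - 1L, end = log_end,   # half-open frame interval
      imd_start = log_imd0, imd_end = log_imd1, completed = log_done
    )
    list(X = X, Y = Y, episodes = ep_log)
  })
}

#' Generate a dyadic pair of centroid tracks
#'
#' Each mouse follows a bounded correlated random walk with attraction to
#' arena corners; during a planted approach episode one mouse steers toward
#' its partner until the inter-mouse distance falls below the contact
#' threshold (a leave episode steers away until the distance exceeds
#' `contact_mm + 100`). Locomotor speed is modulated per frame by
#' `speed_mult` (syllable coupling).
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @param event_plan tibble with columns `animal` (1 or 2), `type`
#'   (`"approach"`/`"leave"`), `t0` and `deadline` (frame indices); may be
#'   empty for undirected wandering.
#' @param speed_mult optional `n_frames x 2` matrix of speed multipliers.
#' @param recording_id id attached to the returned tracks.
#' @return list with `tracks` (two-row track tibble) and `episodes`
#'   (realized episode log with achieved frame intervals and distances).
#' @export
generate_tracks <- function(cfg, seed, event_plan = tibble(animal = integer(),
                                                           type = character(),
                                                           t0 = integer(),
                                                           deadline = integer()),
                            speed_mult = NULL, recording_id = "rec") {
  n_frames <- round(cfg$duration_s * cfg$frame_rate)
  if (nrow(event_plan) && (any(event_plan$t0 < 0) ||
                           any(event_plan$t0 >= n_frames))) {
    abort("event_plan episode outside recording bounds")
  }
  if (is.null(speed_mult)) speed_mult <- matrix(1, n_frames, 2L)
  sim <- sim_tracks(n_frames, 2L, cfg$arena_mm, 1 / cfg$frame_rate,
                    partner = c(2L, 1L), episodes = event_plan,
                    speed_mult = speed_mult, cfg = cfg, seed = seed)
  tracks <- bind_rows(
    centroid_track(recording_id, "m1", sim$X[, 1], sim$Y[, 1], cfg$arena_mm),
    centroid_track(recording_id, "m2", sim$X[, 2], sim$Y[, 2], cfg$arena_mm)
  )
  list(tracks = tracks, episodes = sim$episodes)
}

#' Generate scored contact annotations from a pair of tracks
#'
#' Frames with inter-mouse distance below `cfg$contact_mm` form candidate
#' contact runs (runs shorter than `min_frames` are dropped); each run is
#' scored `active` with probability `cfg$active_prob`, else `passive`.
#'
#' @param xA,yA,xB,yB coordinate vectors of the two animals.
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @param recording_id id attached to the bouts.
#' @param min_frames minimum run length retained.
#' @return annotation tibble (`recording_id`, `contact_type`, `start`,
#'   `end`), unpooled.
#' @export
generate_contacts <- function(xA, yA, xB, yB, cfg, seed,
                              recording_id = "rec", min_frames = 5L) {
  if (length(xA) != length(xB)) abort("tracks must have equal length")
  imd <- sqrt((xA - xB)^2 + (yA - yB)^2)
  prox <- imd < cfg$contact_mm
  r <- rle(prox)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_frames
  if (!any(keep)) {
    return(tibble(recording_id = character(), contact_type = character(),
                  start = integer(), end = integer()))
  }
  s <- starts[keep]; e <- ends[keep]
  with_seed(seed, {
    type <- ifelse(runif(length(s)) < cfg$active_prob, "active", "passive")
    tibble(recording_id = recording_id, contact_type = type,
           start = as.integer(s), end = as.integer(e))
  })
}

# draw a member triple of a syntax family (Hamming distance <= 1)
draw_family_member <- function(ref, n_syllables) {
  if (runif(1) < 0.5) return(ref)
  pos <- sample.int(3L, 1L)
  out <- ref
  repeat {
    cand <- sample.int(n_syllables, 1L) - 1L
    out[pos] <- cand
    if (out[1] != out[2] && out[2] != out[3]) break
  }
  out
}

# overwrite labels[start..end) with tiled family triples (bout length drawn
# from the calibrated geometric), in place
overwrite_with_family <- function(labels, start, end, ref, cfg) {
  p_geom <- geom_prob_for_median(cfg$duration_median_frames)
  f <- start + 1L   # 1-based
  while (f <= end) {
    triple <- draw_family_member(ref, cfg$n_syllables)
    for (s in triple) {
      if (f > end) break
      d <- 1L + rgeom(1L, p_geom)
      hi <- min(f + d - 1L, end)
      labels[f:hi] <- s
      f <- hi + 1L
    }
  }
  labels
}

#' Simulate a complete synthetic experiment
#'
#' Generates solitary and dyadic recordings at the configured study
#' conditions: per-context transition matrices with planted effects,
#' semi-Markov syllable sequences, paired centroid tracks with planted
#' approach/leave episodes (coupled to the two reference syntax families),
#' scored contact annotations, and a planted composition shift during
#' active contact. All randomness derives from `cfg$seed` via named
#' substreams, so two calls with the same configuration are identical.
#'
#' @param cfg a [synthetic_config()].
#' @return a list of class `soseq_experiment` with elements `sequences`,
#'   `tracks`, `annotations` (unpooled), `ground_truth` (planted DM set,
#'   base matrices, realized episode log, substream seeds) and `config`.
#' @export
simulate_experiment <- function(cfg = synthetic_config()) {
  n_frames <- round(cfg$duration_s * cfg$frame_rate)
  n_anim <- cfg$n_animals_per_context
  seeds <- derive_seeds(cfg$seed, c(
    "seq_solitary", "seq_dyadic", "tracks_solitary", "tracks_dyadic",
    "events", "contacts", "bias", "rebalance"
  ))
  mats_sol <- generate_transition_matrices(cfg, "solitary", n_anim)
  mats_dya <- generate_transition_matrices(cfg, "dyadic", n_anim)

  animal_ids <- sprintf("m%02d", seq_len(n_anim))
  light <- rep(c("normal", "reversed"), each = ceiling(n_anim / 2))[seq_len(n_anim)]

  seq_seeds_sol <- derive_seeds(seeds[["seq_solitary"]], animal_ids)
  seq_seeds_dya <- derive_seeds(seeds[["seq_dyadic"]], animal_ids)
  labels_sol <- lapply(seq_len(n_anim), function(a) {
    generate_sequence(mats_sol$animals[[a]], cfg, seq_seeds_sol[[a]])
  })
  labels_dya <- lapply(seq_len(n_anim), function(a) {
    generate_sequence(mats_dya$animals[[a]], cfg, seq_seeds_dya[[a]])
  })

  # ---- tracks -------------------------------------------------------------
  planted1 <- cfg$planted_dm + 1L
  mult_for <- function(lab) ifelse((lab + 1L) %in% planted1, cfg$dm_speed_factor, 1)
  n_pairs <- n_anim %/% 2L
  pair_of <- rep(seq_len(n_pairs), each = 2L)
  partner <- as.integer(seq_len(n_anim) + c(1L, -1L))

  # planted episode schedule: alternating approach/leave slots per pair,
  # assigned to the first animal of each pair
  ev <- with_seed(seeds[["events"]], {
    n_ep <- cfg$n_approach + cfg$n_leave
    slot <- floor((n_frames - 2L * cfg$frame_rate) / max(n_ep, 1L))
    out <- list()
    for (p in seq_len(n_pairs)) {
      types <- c(rep("approach", cfg$n_approach), rep("leave", cfg$n_leave))
      types <- types[sample.int(n_ep)]
      t0 <- (seq_len(n_ep) - 1L) * slot + sample.int(max(slot %/% 4L, 1L), n_ep, replace = TRUE)
      out[[p]] <- tibble(animal = 2L * p - 1L, type = types,
                         t0 = as.integer(t0),
                         deadline = as.integer(pmin(t0 + slot - 1L, n_frames - 1L)))
    }
    bind_rows(out)
  })

  speed_dya <- vapply(labels_dya, mult_for, numeric(n_frames))
  sim_d <- sim_tracks(n_frames, n_anim, cfg$arena_mm, 1 / cfg$frame_rate,
                      partner, ev, speed_dya, cfg, seeds[["tracks_dyadic"]])
  speed_sol <- vapply(labels_sol, mult_for, numeric(n_frames))
  sim_s <- sim_tracks(n_frames, n_anim, cfg$arena_mm, 1 / cfg$frame_rate,
                      rep(NA_integer_, n_anim),
                      tibble(animal = integer(), type = character(),
                             t0 = integer(), deadline = integer()),
                      speed_sol, cfg, seeds[["tracks_solitary"]])

  # ---- family coupling: overwrite steering animal's labels during episodes
  # keep the pure matrix-process labels so whole-recording bout composition
  # can be restored after the temporally localized plantings below
  labels_base <- labels_dya
  win_s <- rep(list(integer()), n_anim)
  win_e <- rep(list(integer()), n_anim)
  eps <- sim_d$episodes
  with_seed(seeds[["bias"]], {
    if (nrow(eps)) {
      for (i in seq_len(nrow(eps))) {
        a <- eps$animal[i]
        ref <- if (eps$type[i] == "approach") cfg$family_syntaxes$approach else cfg$family_syntaxes$leave
        labels_dya[[a]] <- overwrite_with_family(labels_dya[[a]], eps$start[i],
                                                 eps$end[i], ref, cfg)
        win_s[[a]] <- c(win_s[[a]], eps$start[i])
        win_e[[a]] <- c(win_e[[a]], eps$end[i])
      }
    }
  })

  # ---- contacts + planted contact composition ----------------------------
  contact_seeds <- derive_seeds(seeds[["contacts"]], sprintf("p%02d", seq_len(n_pairs)))
  bias_seeds <- derive_seeds(seeds[["bias"]], sprintf("p%02d", seq_len(n_pairs)))
  rec_ids_d <- sprintf("D%02d", seq_len(n_pairs))
  annotations <- list()
  bias_w <- rep(1, cfg$n_syllables)
  bias_w[cfg$contact_bias_ids + 1L] <- cfg$contact_bias_strength
  bias_w <- bias_w / sum(bias_w)
  for (p in seq_len(n_pairs)) {
    a1 <- 2L * p - 1L; a2 <- 2L * p
    ann <- generate_contacts(sim_d$X[, a1], sim_d$Y[, a1],
                             sim_d$X[, a2], sim_d$Y[, a2],
                             cfg, contact_seeds[[p]], rec_ids_d[p])
    annotations[[p]] <- ann
    act <- ann[ann$contact_type == "active", ]
    if (nrow(act)) {
      with_seed(bias_seeds[[p]], {
        for (a in c(a1, a2)) {
          lab <- labels_dya[[a]]
          for (i in seq_len(nrow(act))) {
            s0 <- act$start[i]; e0 <- act$end[i]
            if (runif(1) < cfg$contact_syntax_prob) {
              span <- min(3L * cfg$duration_median_frames, n_frames - s0)
              if (span >= 3L) {
                lab <- overwrite_with_triple(lab, s0, s0 + span,
                                             cfg$contact_syntax,
                                             cfg$duration_median_frames)
              }
            }
            # redraw bouts overlapping the run from the biased composition
            if (cfg$contact_syllable_prob > 0 && e0 > s0) {
              iv <- rle_intervals(lab[(s0 + 1L):e0])
              redraw <- runif(nrow(iv)) < cfg$contact_syllable_prob
              if (any(redraw)) {
                new_s <- sample.int(cfg$n_syllables, sum(redraw),
                                    replace = TRUE, prob = bias_w) - 1L
                iv$syllable[redraw] <- new_s
                lab[(s0 + 1L):e0] <- rep.int(iv$syllable, iv$end - iv$start)
              }
            }
          }
          labels_dya[[a]] <- lab
          win_s[[a]] <- c(win_s[[a]], act$start)
          win_e[[a]] <- c(win_e[[a]], pmax(act$end, pmin(
            act$start + 3L * cfg$duration_median_frames, n_frames)))
        }
      })
    }
  }
  annotations <- bind_rows(annotations)

  # ---- restore whole-recording bout composition ---------------------------
  # the contact/episode plantings above concentrate target syllables inside
  # their windows; compensating relabels outside the windows keep each
  # animal's overall bout counts close to the matrix process, so the planted
  # usage (DM) effect remains the only whole-recording modulation
  rebal_seeds <- derive_seeds(seeds[["rebalance"]], animal_ids)
  for (a in seq_len(n_anim)) {
    if (length(win_s[[a]])) {
      labels_dya[[a]] <- rebalance_bout_counts(
        labels_base[[a]], labels_dya[[a]], win_s[[a]], win_e[[a]],
        cfg$n_syllables, rebal_seeds[[a]])
    }
  }

  # ---- assemble tibbles ---------------------------------------------------
  sequences <- bind_rows(
    bind_rows(lapply(seq_len(n_anim), function(a) {
      syllable_sequence(sprintf("S%02d", a), animal_ids[a], "solitary",
                        labels_sol[[a]], light[a], cfg$frame_rate)
    })),
    bind_rows(lapply(seq_len(n_anim), function(a) {
      syllable_sequence(rec_ids_d[pair_of[a]], animal_ids[a], "dyadic",
                        labels_dya[[a]], light[a], cfg$frame_rate)
    }))
  )
  tracks <- bind_rows(
    bind_rows(lapply(seq_len(n_anim), function(a) {
      centroid_track(sprintf("S%02d", a), animal_ids[a],
                     sim_s$X[, a], sim_s$Y[, a], cfg$arena_mm)
    })),
    bind_rows(lapply(seq_len(n_anim), function(a) {
      centroid_track(rec_ids_d[pair_of[a]], animal_ids[a],
                     sim_d$X[, a], sim_d$Y[, a], cfg$arena_mm)
    }))
  )
  eps$recording_id <- rec_ids_d[pair_of[eps$animal]]
  eps$animal_id <- animal_ids[eps$animal]
  k_dm <- length(cfg$planted_dm)
  # expected onset-proportion modulation is analytic: onset proportions
  # follow the stationary distribution of the bout-level chain, so the
  # expected relative shift per syllable is the ratio of the two base
  # matrices' stationary distributions. Modulating the planted columns
  # necessarily perturbs the stationary mass of some non-planted syllables
  # (network spillover); ids with |expected shift| > 5% are recorded as
  # genuinely modulated even though not planted.
  pi_sol <- stationary_distribution(mats_sol$base)
  pi_dya <- stationary_distribution(mats_dya$base)
  expected_shift <- pi_dya / pi_sol - 1
  spillover_ids <- setdiff(which(abs(expected_shift) > 0.05) - 1L, cfg$planted_dm)
  ground_truth <- list(
    planted_dm = cfg$planted_dm,
    planted_up = cfg$planted_dm[seq_len(ceiling(k_dm / 2))],
    planted_down = cfg$planted_dm[setdiff(seq_len(k_dm), seq_len(ceiling(k_dm / 2)))],
    expected_onset_shift = expected_shift,
    spillover_ids = spillover_ids,
    base_solitary = mats_sol$base,
    base_dyadic = mats_dya$base,
    episodes = eps,
    seeds = seeds
  )
  structure(list(sequences = sequences, tracks = tracks,
                 annotations = annotations, ground_truth = ground_truth,
                 config = cfg),
            class = "soseq_experiment")
}

# Stationary distribution of a row-stochastic matrix by power iteration.
stationary_distribution <- function(P, tol = 1e-13, max_iter = 1e5) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(max_iter)) {
    v2 <- as.vector(v %*% P)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# Restore whole-recording bout composition after localized plantings.
#
# `before` holds the labels produced by the pure matrix process, `after` the
# labels with contact/episode plantings applied inside the windows
# [win_s, win_e). Per-syllable bout-count surpluses created by the planting
# are cancelled by relabeling randomly chosen surplus-id bouts lying fully
# outside the windows with deficit ids, so the planting becomes a temporal
# redistribution of syllable usage (as in contact association) rather than a
# usage change. Neutrality is approximate: relabels that would merge equal
# neighbors are skipped.
rebalance_bout_counts <- function(before, after, win_s, win_e, n_syl, seed) {
  with_seed(seed, {
    c0 <- tabulate(rle(before)$values + 1L, nbins = n_syl)
    iv <- rle_intervals(after)
    c1 <- tabulate(iv$syllable + 1L, nbins = n_syl)
    delta <- c1 - c0
    if (all(delta == 0L)) return(after)
    n_frames <- length(after)
    mask <- logical(n_frames)
    for (k in seq_along(win_s)) {
      lo <- max(win_s[k] + 1L, 1L)
      hi <- min(win_e[k], n_frames)
      if (lo <= hi) mask[lo:hi] <- TRUE
    }
    cs <- c(0L, cumsum(mask))
    covered <- (cs[iv$end + 1L] - cs[iv$start + 1L]) > 0L
    deficit <- rep.int(which(delta < 0L), -delta[delta < 0L])
    if (length(deficit) > 1L) deficit <- deficit[sample.int(length(deficit))]
    di <- 1L
    for (id1 in which(delta > 0L)) {
      cand <- which(!covered & iv$syllable == id1 - 1L)
      take <- min(delta[id1], length(cand), length(deficit) - di + 1L)
      if (take <= 0L) next
      pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), take)]
      for (b in pick) {
        if (di > length(deficit)) break
        new_id <- deficit[di] - 1L
        prev <- if (b > 1L) iv$syllable[b - 1L] else -2L
        nxt <- if (b < nrow(iv)) iv$syllable[b + 1L] else -2L
        if (new_id == prev || new_id == nxt) next
        after[(iv$start[b] + 1L):iv$end[b]] <- new_id
        iv$syllable[b] <- new_id
        di <- di + 1L
      }
    }
    after
  })
}

# tile a fixed triple over labels[start..end) with ~median-length bouts
overwrite_with_triple <- function(labels, start, end, triple, med) {
  f <- start + 1L
  for (s in triple) {
    hi <- min(f + med - 1L, end)
    if (f > hi) break
    labels[f:hi] <- s
    f <- hi + 1L
  }
  labels
}

#' @export
print.soseq_experiment <- function(x, ...) {
  cat("<soseq_experiment>\n")
  cat(sprintf("  %d sequences (%d solitary, %d dyadic), %d tracks, %d contact bouts\n",
              nrow(x$sequences), sum(x$sequences$context == "solitary"),
              sum(x$sequences$context == "dyadic"), nrow(x$tracks),
              nrow(x$annotations)))
  cat(sprintf("  planted DM syllables: %s\n",
              paste(x$ground_truth$planted_dm, collapse = ", ")))
  invisible(x)
}

#' Write and read an experiment directory
#'
#' `write_experiment()` serializes an experiment to the plain-text artifact
#' formats (per animal-recording `*.labels.csv` + `*.meta.json` +
#' `*.track.csv`, per dyadic recording `*.annotations.csv`, plus
#' `ground_truth.json`). `read_experiment()` reads such a directory back
#' into the in-memory form. Writing then reading is the identity on the
#' sequences, tracks and annotations tables.
#'
#' @param experiment a `soseq_experiment`.
#' @param dir target directory (created if needed).
#' @return `write_experiment()` the directory, invisibly;
#'   `read_experiment()` a `soseq_experiment` (without base matrices if the
#'   ground truth file is absent).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- experiment$sequences
  for (i in seq_len(nrow(seqs))) {
    stem <- file.path(dir, sprintf("%s_%s", seqs$recording_id[i], seqs$animal_id[i]))
    write_labels(seqs[i, ], paste0(stem, ".labels.csv"),
                 paste0(stem, ".meta.json"))
  }
  trks <- experiment$tracks
  for (i in seq_len(nrow(trks))) {
    stem <- file.path(dir, sprintf("%s_%s", trks$recording_id[i], trks$animal_id[i]))
    write_track(trks[i, ], paste0(stem, ".track.csv"))
  }
  for (rid in unique(experiment$annotations$recording_id)) {
    write_annotations(experiment$annotations[experiment$annotations$recording_id == rid, ],
                      file.path(dir, paste0(rid, ".annotations.csv")))
  }
  gt <- experiment$ground_truth
  if (!is.null(gt)) {
    jsonlite::write_json(list(
      planted_dm = gt$planted_dm,
      planted_up = gt$planted_up,
      planted_down = gt$planted_down,
      expected_onset_shift = gt$expected_onset_shift,
      spillover_ids = gt$spillover_ids,
      base_solitary = gt$base_solitary,
      base_dyadic = gt$base_dyadic,
      episodes = gt$episodes,
      seeds = as.list(gt$seeds)
    ), file.path(dir, "ground_truth.json"), digits = NA)
  }
  jsonlite::write_json(
    experiment$config[!vapply(experiment$config, is.list, logical(1))],
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  lab_files <- sort(list.files(dir, pattern = "\\.labels\\.csv$", full.names = TRUE))
  if (!length(lab_files)) abort(sprintf("no label files in %s", dir))
  sequences <- bind_rows(lapply(lab_files, function(f) {
    read_labels(f, sub("\\.labels\\.csv$", ".meta.json", f))
  }))
  trk_files <- sort(list.files(dir, pattern = "\\.track\\.csv$", full.names = TRUE))
  tracks <- bind_rows(lapply(trk_files, function(f) {
    stem <- sub("\\.track\\.csv$", "", basename(f))
    parts <- strsplit(stem, "_")[[1]]
    read_track(f, parts[1], parts[2])
  }))
  ann_files <- sort(list.files(dir, pattern = "\\.annotations\\.csv$", full.names = TRUE))
  annotations <- if (length(ann_files)) {
    bind_rows(lapply(ann_files, function(f) {
      read_annotations(f, sub("\\.annotations\\.csv$", "", basename(f)),
                       pooling_gap_s = NULL)
    }))
  } else {
    tibble(recording_id = character(), contact_type = character(),
           start = integer(), end = integer())
  }
  gt_file <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_file)) {
    g <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    g$base_solitary <- as.matrix(g$base_solitary)
    g$base_dyadic <- as.matrix(g$base_dyadic)
    g$episodes <- as_tibble(g$episodes)
    g
  } else NULL
  cfg_file <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_file)) jsonlite::read_json(cfg_file, simplifyVector = TRUE) else NULL
  structure(list(sequences = sequences, tracks = tracks,
                 annotations = annotations, ground_truth = gt, config = cfg),
            class = "soseq_experiment")
}
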