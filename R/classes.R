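# Parametric social-behavior classes in (IMD, CID) space and the
# position/distance controls.

#' Classify kinematic points into parametric behavior classes
#'
#' A point has `x` = inter-mouse distance (mm) at the start of a syntax (or
#' window) and `y` = change in that distance by its end. The four classes
#' partition the plane at the contact threshold (100 mm by default):
#' contact (`x < 100, x + y < 100`), approach (`x > 100, x + y < 100`),
#' leave (`x < 100, x + y > 100`) and far_stationary
#' (`x > 100, x + y > 100`). Boundary equalities go to the stationary side
#' (contact/far_stationary) and are counted. Control classes match the
#' distance change while excluding contact: approach_control
#' (`y < 0, x + y > 100`) and leave_control (`y > 0, x > 100`).
#'
#' @param x,y numeric vectors (mm); `x` must be non-negative.
#' @param contact_mm threshold (mm).
#' @return tibble `x`, `y`, `class`, `control_class` (`NA` when in
#'   neither control region), `boundary` (logical).
#' @export
classify_kinematics <- function(x, y, contact_mm = 100) {
  if (any(x < 0, na.rm = TRUE)) abort("inter-mouse distance x must be non-negative")
  s <- x + y
  cls <- dplyr::case_when(
    x > contact_mm & s < contact_mm ~ "approach",
    x < contact_mm & s > contact_mm ~ "leave",
    x <= contact_mm & s <= contact_mm ~ "contact",
    TRUE ~ "far_stationary"
  )
  ctrl <- dplyr::case_when(
    y < 0 & s > contact_mm ~ "approach_control",
    y > 0 & x > contact_mm ~ "leave_control",
    TRUE ~ NA_character_
  )
  boundary <- x == contact_mm | s == contact_mm
  if (any(boundary, na.rm = TRUE)) {
    inform(sprintf("%d boundary point(s) assigned to the stationary side",
                   sum(boundary, na.rm = TRUE)))
  }
  tibble(x = x, y = y, class = cls, control_class = ctrl,
         boundary = boundary)
}

#' Kinematic points of syntax occurrences
#'
#' @param syntaxes output of [extract_syntaxes()].
#' @param imd_by_recording named list of per-recording inter-mouse distance
#'   series.
#' @param contact_mm threshold passed to [classify_kinematics()].
#' @return `syntaxes` with columns `x`, `y`, `class`, `control_class`
#'   appended (rows without distance data are dropped).
#' @export
syntax_kinematics <- function(syntaxes, imd_by_recording, contact_mm = 100) {
  x <- y <- rep(NA_real_, nrow(syntaxes))
  for (r in unique(syntaxes$recording_id)) {
    s <- imd_by_recording[[r]]
    if (is.null(s)) next
    i <- which(syntaxes$recording_id == r)
    st <- syntaxes$start[i] + 1L
    en <- pmin(syntaxes$end[i], length(s))
    ok <- st <= length(s) & en >= st
    x[i[ok]] <- s[st[ok]]
    y[i[ok]] <- s[en[ok]] - s[st[ok]]
  }
  keep <- !is.na(x) & !is.na(y)
  cls <- classify_kinematics(x[keep], y[keep], contact_mm)
  bind_cols(syntaxes[keep, ], cls[, c("x", "y", "class", "control_class")])
}

#' Inter-mouse distance control histograms
#'
#' Compares the observed inter-mouse distance distribution with two
#' controls: `shuffled` (each animal's position sequence permuted
#' independently in time before taking frame-wise distances, destroying
#' coordination but keeping each animal's spatial occupancy) and `random`
#' (distances between uniform random point pairs in the arena). All three
#' use one shared binning; the observed-minus-shuffled difference is
#' attached.
#'
#' @param tracks dyadic track tibble (two rows per recording).
#' @param seed integer seed.
#' @param n_pairs random-control sample size.
#' @param breaks histogram bin edges (mm).
#' @return list of class `soseq_imd_controls`: `histogram` (long tibble
#'   `bin_mid`, `series`, `density`), `difference`, plus the raw means.
#' @export
imd_controls <- function(tracks, seed = 1L, n_pairs = 1e5,
                         breaks = seq(0, 700, by = 10)) {
  recs <- unique(tracks$recording_id)
  observed <- c(); shuffled <- c()
  arena <- c(tracks$arena_w_mm[1], tracks$arena_h_mm[1])
  with_seed(seed, {
    for (r in recs) {
      tr <- tracks[tracks$recording_id == r, ]
      if (nrow(tr) != 2L) next
      observed <- c(observed, imd_series(tr))
      i1 <- sample.int(length(tr$x[[1]]))
      i2 <- sample.int(length(tr$x[[2]]))
      shuffled <- c(shuffled, sqrt((tr$x[[1]][i1] - tr$x[[2]][i2])^2 +
                                     (tr$y[[1]][i1] - tr$y[[2]][i2])^2))
    }
    rnd <- sqrt((runif(n_pairs, 0, arena[1]) - runif(n_pairs, 0, arena[1]))^2 +
                  (runif(n_pairs, 0, arena[2]) - runif(n_pairs, 0, arena[2]))^2)
    hb <- function(v) {
      h <- graphics::hist(pmin(v, max(breaks)), breaks = breaks, plot = FALSE)
      h$density
    }
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    hist_tbl <- bind_rows(
      tibble(bin_mid = mids, series = "observed", density = hb(observed)),
      tibble(bin_mid = mids, series = "shuffled", density = hb(shuffled)),
      tibble(bin_mid = mids, series = "random", density = hb(rnd))
    )
    diff_tbl <- tibble(bin_mid = mids,
                       difference = hb(observed) - hb(shuffled))
    structure(list(histogram = hist_tbl, difference = diff_tbl,
                   mean_observed = mean(observed),
                   mean_shuffled = mean(shuffled),
                   mean_random = mean(rnd)),
              class = "soseq_imd_controls")
  })
}

#' Association between syntax families and behavior classes
#'
#' For each family, a (member vs non-member) x class contingency table is
#' tested with a chi-square test, Bonferroni-corrected across families;
#' per-cell standardized residuals summarize the effect.
#'
#' @param classes character vector of class labels per syntax occurrence.
#' @param memberships named list of logical membership vectors (one per
#'   family), same length as `classes`.
#' @param alpha significance level.
#' @return list of class `soseq_class_association`: `tests` (per-family
#'   tibble), `residuals` (named list of matrices).
#' @export
class_family_association <- function(classes, memberships, alpha = 0.05) {
  if (length(unique(classes)) < 2L) abort("need at least 2 classes with counts")
  rows <- list(); resid <- list()
  for (fam in names(memberships)) {
    m <- memberships[[fam]]
    tab <- table(member = factor(m, levels = c(FALSE, TRUE)), class = classes)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      abort(sprintf("degenerate contingency table for family %s", fam))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[[fam]] <- tibble(family = fam, statistic = unname(ct$statistic),
                          df = unname(ct$parameter), p_raw = ct$p.value)
    resid[[fam]] <- ct$stdres
  }
  tests <- bind_rows(rows) %>%
    mutate(p_adjusted = adjust_p(.data$p_raw, "bonferroni"),
           method = "chi2_contingency", correction = "bonferroni",
           significant = .data$p_adjusted < alpha)
  structure(list(tests = tests, residuals = resid, alpha = alpha),
            class = "soseq_class_association")
}

#' @export
tidy.soseq_class_association <- function(x, ...) x$tests

#' Pairwise class divergence of in-syntax syllable composition
#'
#' For every behavior class the syllable identities inside its member
#' syntaxes are pooled into a distribution; pairwise Kullback-Leibler
#' divergences are computed in both directions (`matrix[i, j] =
#' dkl(class_i || class_j)`).
#'
#' @param syntaxes_classified output of [syntax_kinematics()].
#' @param n_syllables vocabulary size.
#' @param pseudocount smoothing for the reference argument.
#' @return matrix with zero diagonal; empty classes are dropped with a
#'   warning.
#' @export
class_dkl_matrix <- function(syntaxes_classified, n_syllables,
                             pseudocount = 1e-6) {
  cls <- sort(unique(syntaxes_classified$class))
  dists <- lapply(cls, function(cl) {
    d <- syntaxes_classified[syntaxes_classified$class == cl, ]
    v <- c(d$s1, d$s2, d$s3)
    if (!length(v)) return(NULL)
    tabulate(v + 1L, nbins = n_syllables) / length(v)
  })
  keep <- !vapply(dists, is.null, logical(1))
  if (any(!keep)) warn(sprintf("empty class(es) dropped: %s",
                               paste(cls[!keep], collapse = ", ")))
  cls <- cls[keep]; dists <- dists[keep]
  n <- length(cls)
  D <- matrix(0, n, n, dimnames = list(cls, cls))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) D[i, j] <- dkl(dists[[i]], dists[[j]], pseudocount)
    }
  }
  D
}

#' Arena position density estimate
#'
#' 2D Gaussian-kernel density of pooled positions on an arena grid
#' (normal-reference bandwidth), axis marginals, and the corner-occupancy
#' fraction (share of positions within `corner_mm` of an arena corner).
#'
#' @param tracks track tibble.
#' @param grid_n grid resolution per axis.
#' @param corner_mm corner radius (mm).
#' @return list of class `soseq_position_kde`: `kde` (list `x`, `y`, `z`),
#'   `marginal_x`, `marginal_y` (densities), `corner_fraction`, `n`.
#' @export
position_kde <- function(tracks, grid_n = 101L, corner_mm = 100) {
  x <- unlist(tracks$x); y <- unlist(tracks$y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 100L) abort("need at least 100 positions")
  w <- tracks$arena_w_mm[1]; h <- tracks$arena_h_mm[1]
  kde <- MASS::kde2d(x, y, n = grid_n, lims = c(0, w, 0, h))
  corners <- rbind(c(0, 0), c(w, 0), c(0, h), c(w, h))
  dmin <- rep(Inf, length(x))
  for (k in 1:4) {
    dmin <- pmin(dmin, sqrt((x - corners[k, 1])^2 + (y - corners[k, 2])^2))
  }
  structure(list(kde = kde,
                 marginal_x = density(x, from = 0, to = w),
                 marginal_y = density(y, from = 0, to = h),
                 corner_fraction = mean(dmin < corner_mm),
                 n = length(x)),
            class = "soseq_position_kde")
}
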