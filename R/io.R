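#' Analysis configuration defaults
#'
#' Bundles the global tuning parameters shared across the pipeline stages:
#' the significance level, the onset-proportion retention threshold, the
#' syntax length, the contact-bout pooling gap, the pre-contact control
#' window, the contact distance threshold, and the rolling-window length.
#'
#' @param alpha significance level for all corrected tests.
#' @param onset_threshold minimum pooled onset proportion for a syllable to
#'   be retained (strictly greater than).
#' @param syntax_length number of consecutive bouts forming a syntax.
#' @param pooling_gap_s same-type contact bouts separated by a gap shorter
#'   than this many seconds are merged.
#' @param pre_contact_window_s clean control window required before a scored
#'   contact bout, in seconds (125 frames at 25 Hz).
#' @param contact_mm inter-mouse distance threshold (mm) defining proximity.
#' @param rolling_window_frames rolling window length (frames) for the
#'   occupancy vs change-in-distance analysis.
#'
#' @return a named list of class `soseq_config`.
#' @export
analysis_config <- function(alpha = 0.05,
                            onset_threshold = 0.005,
                            syntax_length = 3L,
                            pooling_gap_s = 6,
                            pre_contact_window_s = 5,
                            contact_mm = 100,
                            rolling_window_frames = 30L) {
  cfg <- list(
    alpha = alpha, onset_threshold = onset_threshold,
    syntax_length = as.integer(syntax_length),
    pooling_gap_s = pooling_gap_s,
    pre_contact_window_s = pre_contact_window_s,
    contact_mm = contact_mm,
    rolling_window_frames = as.integer(rolling_window_frames)
  )
  structure(cfg, class = c("soseq_config", "list"))
}

#' Construct a syllable sequence record
#'
#' A syllable sequence is one animal's frame-wise integer labels in one
#' recording (25 frames/s by default); `-1` marks unassigned frames.
#' Sequences are stored one row per animal-recording with the label vector
#' as a list-column, so a whole experiment is an ordinary tibble.
#'
#' @param recording_id,animal_id identifiers.
#' @param context `"solitary"` or `"dyadic"`.
#' @param labels integer vector, one label per frame, `-1` = missing.
#' @param light_cycle `"normal"` or `"reversed"`.
#' @param frame_rate frames per second.
#'
#' @return one-row tibble with a `labels` list-column.
#' @export
syllable_sequence <- function(recording_id, animal_id, context, labels,
                              light_cycle = "normal", frame_rate = 25) {
  context <- match.arg(context, c("solitary", "dyadic"))
  light_cycle <- match.arg(light_cycle, c("normal", "reversed"))
  labels <- as.integer(labels)
  if (length(labels) == 0L) abort("labels must be non-empty")
  if (any(labels < -1L, na.rm = TRUE)) abort("labels must be >= -1")
  if (anyNA(labels)) abort("labels must not contain NA; use -1 for missing")
  if (frame_rate <= 0) abort("frame_rate must be positive")
  tibble(
    recording_id = as.character(recording_id),
    animal_id = as.character(animal_id),
    context = context, light_cycle = light_cycle,
    frame_rate = frame_rate, labels = list(labels)
  )
}

#' Construct a centroid track record
#'
#' Per-frame 2D body-centre positions in arena millimetres. Missing frames
#' are `NA` in both coordinates.
#'
#' @param recording_id,animal_id identifiers.
#' @param x,y numeric coordinate vectors (mm), equal length.
#' @param arena_mm arena side lengths, length-2 (width, depth) or scalar.
#'
#' @return one-row tibble with `x` and `y` list-columns.
#' @export
centroid_track <- function(recording_id, animal_id, x, y, arena_mm = c(453, 453)) {
  if (length(arena_mm) == 1L) arena_mm <- rep(arena_mm, 2L)
  if (length(x) != length(y)) abort("x and y must have equal length")
  miss <- is.na(x) | is.na(y)
  out_of_arena <- !miss & (x < 0 | y < 0 | x > arena_mm[1] | y > arena_mm[2])
  if (any(out_of_arena)) {
    abort(sprintf(
      "position outside arena at frame %d", which(out_of_arena)[1] - 1L
    ))
  }
  tibble(
    recording_id = as.character(recording_id),
    animal_id = as.character(animal_id),
    arena_w_mm = arena_mm[1], arena_h_mm = arena_mm[2],
    x = list(as.numeric(x)), y = list(as.numeric(y))
  )
}

read_meta <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("recording_id", "animal_id", "context", "light_cycle")
  missing_f <- setdiff(need, names(meta))
  if (length(missing_f)) {
    abort(sprintf("metadata %s lacks field(s): %s", path,
                  paste(missing_f, collapse = ", ")))
  }
  if (!meta$context %in% c("solitary", "dyadic")) {
    abort(sprintf("unknown context '%s' in %s", meta$context, path))
  }
  if (!meta$light_cycle %in% c("normal", "reversed")) {
    abort(sprintf("unknown light_cycle '%s' in %s", meta$light_cycle, path))
  }
  meta$frame_rate <- meta$frame_rate %||% 25
  meta
}

default_meta_path <- function(path) sub("\\.csv$", ".meta.json", path)

#' Read and write frame-wise syllable labels
#'
#' `read_labels()` parses a `frame,syllable` CSV plus a JSON metadata sidecar
#' (`recording_id`, `animal_id`, `context`, `light_cycle`, `frame_rate`).
#' Frames must be contiguous from 0; gaps or duplicates are format errors
#' naming the first offending frame.
#'
#' @param path label CSV path.
#' @param meta_path metadata JSON path; defaults to `<path minus .csv>.meta.json`.
#' @return `read_labels()`: a one-row sequence tibble (see
#'   [syllable_sequence()]).
#' @export
read_labels <- function(path, meta_path = default_meta_path(path)) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(), syllable = readr::col_integer()
  ), progress = FALSE)
  if (nrow(d) == 0L) abort(sprintf("%s: empty label file", path))
  expected <- seq.int(0L, nrow(d) - 1L)
  if (anyDuplicated(d$frame)) {
    abort(sprintf("%s: duplicate frame %d", path, d$frame[duplicated(d$frame)][1]))
  }
  if (!identical(sort(d$frame), expected)) {
    first_bad <- setdiff(expected, d$frame)[1]
    abort(sprintf("%s: frame %d missing", path, first_bad))
  }
  d <- arrange(d, .data$frame)
  meta <- read_meta(meta_path)
  syllable_sequence(meta$recording_id, meta$animal_id, meta$context,
                    d$syllable, meta$light_cycle, meta$frame_rate)
}

#' @rdname read_labels
#' @param seq a one-row sequence tibble.
#' @export
write_labels <- function(seq, path, meta_path = default_meta_path(path)) {
  stopifnot(nrow(seq) == 1L)
  labels <- seq$labels[[1]]
  readr::write_csv(tibble(frame = seq_along(labels) - 1L, syllable = labels), path)
  jsonlite::write_json(
    list(recording_id = seq$recording_id, animal_id = seq$animal_id,
         context = seq$context, light_cycle = seq$light_cycle,
         frame_rate = seq$frame_rate),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read and write centroid tracks
#'
#' `read_track()` parses a `frame,x_mm,y_mm` CSV directly;
#' `read_keypoints()` parses a `frame,point,x_mm,y_mm` CSV with exactly 10
#' body points per frame and reduces each frame to the coordinate-wise
#' median of the points (the body-centre convention for 10 tracked body
#' points, tail excluded). NaN coordinates are marked missing and counted in
#' a message.
#'
#' @param path CSV path.
#' @param recording_id,animal_id identifiers attached to the track.
#' @param arena_mm arena size in mm, passed to [centroid_track()].
#' @return a one-row track tibble (see [centroid_track()]).
#' @export
read_track <- function(path, recording_id = "rec", animal_id = "animal",
                       arena_mm = c(453, 453)) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(), x_mm = readr::col_double(),
    y_mm = readr::col_double()
  ), progress = FALSE)
  d <- arrange(d, .data$frame)
  n_miss <- sum(is.na(d$x_mm) | is.na(d$y_mm))
  if (n_miss > 0) inform(sprintf("%s: %d frame(s) with missing coordinates", path, n_miss))
  centroid_track(recording_id, animal_id, d$x_mm, d$y_mm, arena_mm)
}

#' @rdname read_track
#' @export
read_keypoints <- function(path, recording_id = "rec", animal_id = "animal",
                           arena_mm = c(453, 453)) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(), point = readr::col_integer(),
    x_mm = readr::col_double(), y_mm = readr::col_double()
  ), progress = FALSE)
  counts <- dplyr::count(d, .data$frame)
  bad <- counts$frame[counts$n != 10L]
  if (length(bad)) {
    abort(sprintf("%s: frame %d has %d points (expected 10)", path, bad[1],
                  counts$n[counts$frame == bad[1]][1]))
  }
  cen <- d %>%
    group_by(.data$frame) %>%
    summarise(x_mm = median(.data$x_mm), y_mm = median(.data$y_mm),
              .groups = "drop") %>%
    arrange(.data$frame)
  n_miss <- sum(is.na(cen$x_mm) | is.na(cen$y_mm))
  if (n_miss > 0) inform(sprintf("%s: %d frame(s) with missing centroid", path, n_miss))
  centroid_track(recording_id, animal_id, cen$x_mm, cen$y_mm, arena_mm)
}

#' @rdname read_track
#' @param track a one-row track tibble.
#' @export
write_track <- function(track, path) {
  stopifnot(nrow(track) == 1L)
  readr::write_csv(tibble(
    frame = seq_along(track$x[[1]]) - 1L,
    x_mm = track$x[[1]], y_mm = track$y[[1]]
  ), path)
  invisible(path)
}

#' Read, pool and write scored contact annotations
#'
#' Annotations are experimenter-scored contact bouts
#' (`contact_type,start_frame,end_frame`, half-open frame intervals,
#' `active` = directed sniffing contact, `passive` = body contact without
#' sniffing). On read, bouts of the same type separated by a gap strictly
#' shorter than `pooling_gap_s` seconds (150 frames at 25 Hz for the 6 s
#' default) are merged, which guarantees that a clean 5 s pre-contact
#' control window can be placed before each retained bout onset.
#'
#' @param path CSV path.
#' @param recording_id identifier attached to the bouts.
#' @param frame_rate frames per second used to convert the pooling gap.
#' @param pooling_gap_s merge gap threshold in seconds; `NULL` disables
#'   pooling.
#' @return tibble with columns `recording_id`, `contact_type`, `start`, `end`.
#' @export
read_annotations <- function(path, recording_id = "rec", frame_rate = 25,
                             pooling_gap_s = 6) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- readr::read_csv(path, col_types = readr::cols(
    contact_type = readr::col_character(),
    start_frame = readr::col_integer(), end_frame = readr::col_integer()
  ), progress = FALSE)
  bad_type <- setdiff(unique(d$contact_type), c("active", "passive"))
  if (length(bad_type)) abort(sprintf("%s: unknown contact_type '%s'", path, bad_type[1]))
  bad <- which(d$end_frame <= d$start_frame)
  if (length(bad)) {
    abort(sprintf("%s: row %d has end <= start", path, bad[1]))
  }
  out <- tibble(recording_id = recording_id, contact_type = d$contact_type,
                start = d$start_frame, end = d$end_frame)
  if (!is.null(pooling_gap_s)) {
    out <- pool_annotations(out, gap_frames = round(pooling_gap_s * frame_rate))
  }
  arrange(out, .data$start)
}

#' @rdname read_annotations
#' @param annotations annotation tibble as returned unpooled.
#' @param gap_frames merge two same-type bouts when the gap between them is
#'   strictly less than this many frames.
#' @export
pool_annotations <- function(annotations, gap_frames = 150) {
  annotations %>%
    group_by(.data$recording_id, .data$contact_type) %>%
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$start)
      start <- d$start; end <- d$end
      keep_start <- start[1]; keep_end <- end[1]
      out_s <- c(); out_e <- c()
      if (nrow(d) > 1L) {
        for (i in 2:nrow(d)) {
          if (start[i] - keep_end < gap_frames) {
            keep_end <- max(keep_end, end[i])
          } else {
            out_s <- c(out_s, keep_start); out_e <- c(out_e, keep_end)
            keep_start <- start[i]; keep_end <- end[i]
          }
        }
      }
      tibble(start = c(out_s, keep_start), end = c(out_e, keep_end))
    }) %>%
    ungroup() %>%
    arrange(.data$recording_id, .data$start)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(tibble(
    contact_type = annotations$contact_type,
    start_frame = annotations$start, end_frame = annotations$end
  ), path)
  invisible(path)
}
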