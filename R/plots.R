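# ggplot2 views of the main result objects.

#' @export
autoplot.soseq_context_modulation <- function(object, ...) {
  d <- object$tests %>%
    mutate(set = ifelse(.data$significant, "DM", "DU"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$syllable),
                                  y = -log10(.data$p_adjusted),
                                  fill = .data$set)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::labs(x = "syllable", y = "-log10 adjusted p",
                  title = "Context modulation of syllable onset proportions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soseq_dkl_timecourse <- function(object, ...) {
  d <- object$course
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset_mid, y = .data$dkl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = d[d$significant, ], color = "red", size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::annotate("rect", xmin = object$baseline[1], xmax = object$baseline[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1) +
    ggplot2::labs(x = "offset from contact onset (frames)",
                  y = "D[KL] (nats)",
                  title = sprintf("%s composition divergence (%s contact)",
                                  if (object$joint) "Joint" else "Single-mouse",
                                  object$contact_type)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soseq_rolling_relation <- function(object, ...) {
  s <- object$summary
  s$mid <- vapply(as.character(s$bin), function(b) {
    v <- as.numeric(strsplit(gsub("[\\(\\)\\[\\]]", "", b), ",")[[1]])
    mean(v)
  }, numeric(1))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mid, y = .data$median_occ)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "change in inter-mouse distance over window (mm)",
                  y = "family occupancy fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soseq_pca <- function(object, colour = "context", ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soseq_imd_controls <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid, y = .data$density,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "inter-mouse distance (mm)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory-similarity dendrogram
#'
#' @param x a `soseq_dendrogram`.
#' @param ... passed to [plot()].
#' @export
plot.soseq_dendrogram <- function(x, ...) {
  plot(x$hclust, xlab = "syllable", sub = "",
       main = "Inter-syllable trajectory cosine distance", ...)
}
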