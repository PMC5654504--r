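#' Plot a 96-context mutation spectrum
#'
#' Bar chart of class fractions in the conventional layout: one panel per
#' substitution type, contexts on the horizontal axis.
#'
#' @param object A `"mutation_spectrum"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mutation_spectrum <- function(object, ...) {
  df <- tidy.mutation_spectrum(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context, y = .data$fraction,
                                   fill = .data$type)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(. ~ type, scales = "free_x") +
    ggplot2::labs(x = "trinucleotide context", y = "fraction of SNVs",
                  title = sprintf("Mutation spectrum: %s", object$sample_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5))
}

#' Plot VAF trajectories over time
#'
#' One line per variant across sampling days; undetected timepoints appear at
#' VAF 0. Colouring by a cluster assignment (from [cluster_trajectories()])
#' highlights subclone structure.
#'
#' @param object A `"vaf_matrix"`.
#' @param clusters Optional `"subclone_clusters"` for colouring.
#' @param imaging_day Optional day to mark with a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vaf_matrix <- function(object, clusters = NULL, imaging_day = NULL,
                                ...) {
  df <- tidy.vaf_matrix(object)
  if (!is.null(clusters)) {
    df <- left_join(df, tidy.subclone_clusters(clusters), by = "variant") |>
      mutate(cluster = factor(.data$cluster))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$vaf,
                                          group = .data$variant,
                                          colour = .data$cluster))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$vaf,
                                          group = .data$variant))
  }
  p <- p + ggplot2::geom_line(alpha = 0.5) + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "day relative to treatment start",
                  y = "variant allele frequency") +
    ggplot2::theme_minimal()
  if (!is.null(imaging_day)) {
    p <- p + ggplot2::geom_vline(xintercept = imaging_day, linetype = "dashed")
  }
  p
}

#' Plot a simulated fragment-length distribution
#'
#' Histogram of fragment lengths with the modal length annotated; the 10-base
#' sub-peaks below the mode are the nucleosome-periodicity fingerprint of
#' cfDNA.
#'
#' @param lengths Integer vector from [sample_fragment_lengths()].
#' @return A ggplot object.
#' @export
plot_fragment_lengths <- function(lengths) {
  df <- dplyr::count(tibble(length = lengths), .data$length)
  mode_len <- df$length[which.max(df$n)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = mode_len, linetype = "dashed") +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments",
                  subtitle = sprintf("mode = %d bp", mode_len)) +
    ggplot2::theme_minimal()
}
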