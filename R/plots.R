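#' Volcano plot of screen enrichment results
#'
#' log2 enrichment score against -log10 p-value, highlighting genes below
#' the given q-value cutoff.
#'
#' @param object An `enrichment_result` from [screen_enrichment()].
#' @param q_cutoff Significance highlight threshold (BH q-value).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, q_cutoff = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$q_value < q_cutoff
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_score,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      name = sprintf("q < %.2g", q_cutoff)
    ) +
    ggplot2::labs(
      x = "log2 enrichment score (sorted / control)",
      y = "-log10 p (Student t, two-tailed)",
      title = sprintf("Screen enrichment: %s vs control",
                      attr(object, "contrast"))
    ) +
    ggplot2::theme_minimal()
}

#' Lorenz curve of library representation
#'
#' Cumulative share of reads against cumulative share of members for one
#' sample; the diagonal is a perfectly uniform library and the gap to it
#' is summarised by the Gini coefficient.
#'
#' @param counts Long count tibble.
#' @param sample Sample to plot (required when counts span several).
#' @return A ggplot object.
#' @export
plot_lorenz <- function(counts, sample = NULL) {
  qc <- library_uniformity(counts, sample)
  counts <- as_tibble(counts)
  if (!is.null(sample)) {
    smp <- sample
    counts <- filter(counts, .data$sample == smp)
  }
  x <- sort(counts$count)
  df <- tibble(
    member_share = seq_along(x) / length(x),
    read_share = cumsum(x) / sum(x)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$member_share,
                                   y = .data$read_share)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(
      x = "cumulative share of members",
      y = "cumulative share of reads",
      title = sprintf("Library representation, %s (Gini = %.3f, %d dropout%s)",
                      qc$sample, qc$gini, qc$n_missing,
                      if (qc$n_missing == 1) "" else "s")
    ) +
    ggplot2::theme_minimal()
}

#' Guide QC overview for a designed library
#'
#' Distribution of selected-guide GC content, homopolymer run and cut-site
#' position fraction across the library, with the hard-filter bounds
#' marked.
#'
#' @param library A [design_library()] result.
#' @param rules The [design_rules()] used (for the filter bounds).
#' @return A ggplot object.
#' @export
plot_guide_qc <- function(library, rules = design_rules()) {
  df <- as_tibble(library) |>
    select(all_of(c("gene_id", "gc", "max_run", "position_fraction"))) |>
    tidyr::pivot_longer(-"gene_id", names_to = "metric")
  bounds <- tibble(
    metric = c("gc", "max_run", "position_fraction"),
    bound = c(rules$gc_max, rules$max_run, rules$position_fraction_max)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(data = bounds,
                        ggplot2::aes(xintercept = .data$bound),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "selected guides",
                  title = "Selected-guide QC (dashed: filter bound)") +
    ggplot2::theme_minimal()
}
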