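#' Per-gene frequencies from a count table
#'
#' The frequency of a gene in a sample is its read count divided by the
#' sample's total count. A pseudocount (default 0.5) is added to every
#' cell before normalisation so downstream frequency ratios stay finite
#' for dropout members; raw counts are preserved alongside.
#'
#' @param counts Long count tibble (`sample`, `condition`, `replicate`,
#'   `gene_id`, `count`).
#' @param pseudocount Continuity correction added to every cell.
#' @return The input with a `freq` column; frequencies sum to 1 within
#'   each sample.
#' @export
compute_frequency <- function(counts, pseudocount = 0.5) {
  counts <- as_tibble(counts)
  totals <- counts |>
    group_by(.data$sample) |>
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample[totals$total == 0]
  if (length(zero) > 0L && pseudocount == 0) {
    abort(paste0("sample(s) with zero total count: ",
                 paste(zero, collapse = ", ")),
          class = "crisprsort_zero_sample")
  }
  counts |>
    group_by(.data$sample) |>
    mutate(freq = (.data$count + pseudocount) /
             sum(.data$count + pseudocount)) |>
    ungroup()
}

#' Enrichment score: sorted frequency over control frequency
#'
#' @param freq_sorted,freq_control Positive frequencies (means across
#'   replicates); vectors are recycled.
#' @return Tibble with `enrichment_score` and `log2_score`.
#' @export
enrichment_score <- function(freq_sorted, freq_control) {
  if (any(freq_sorted <= 0) || any(freq_control <= 0)) {
    abort("frequencies must be > 0; add a pseudocount upstream")
  }
  score <- freq_sorted / freq_control
  tibble(enrichment_score = score, log2_score = log2(score))
}

#' Two-tailed Student's t-test on replicate frequencies
#'
#' Compares per-replicate frequencies between the sorted and control
#' groups with a pooled-variance two-tailed t-test. The pooled (Student)
#' flavour is used rather than Welch because at the screen's three
#' replicates per pool the Welch-Satterthwaite approximation is
#' measurably conservative, deflating the type-I error below nominal,
#' whereas the pooled test stays calibrated. Degenerate zero-variance
#' groups: identical groups give p = 1; zero variance with differing
#' means gives p = 0 (an exact mean difference with no within-group
#' spread).
#'
#' @param freq_sorted_reps,freq_control_reps Numeric vectors of length
#'   >= 2.
#' @return The two-tailed p-value.
#' @export
test_enrichment <- function(freq_sorted_reps, freq_control_reps) {
  if (length(freq_sorted_reps) < 2L || length(freq_control_reps) < 2L) {
    abort("at least 2 replicates per group are required")
  }
  if (stats::sd(freq_sorted_reps) == 0 && stats::sd(freq_control_reps) == 0) {
    return(if (mean(freq_sorted_reps) == mean(freq_control_reps)) 1 else 0)
  }
  t.test(freq_sorted_reps, freq_control_reps, var.equal = TRUE)$p.value
}

#' Screen enrichment analysis for one contrast
#'
#' The screen statistic: per-replicate frequencies (with pseudocount),
#' their means per group, the enrichment score (mean sorted frequency /
#' mean control frequency) and its log2, a two-tailed Student t-test across
#' replicates, Benjamini-Hochberg q-values across genes, and a rank —
#' descending log2 score for a `max` contrast (enrichment in the
#' high-signal pool), ascending for `min`; ties break by gene id.
#'
#' @param counts Long count tibble containing the `control` condition and
#'   the contrast condition.
#' @param contrast Sorted condition to compare against control
#'   (e.g. `"max"` or `"min"`).
#' @param pseudocount Continuity correction, see [compute_frequency()].
#' @return A tibble of class `enrichment_result`, one row per gene:
#'   `gene_id`, `freq_control` / `freq_sorted` (list columns of replicate
#'   frequencies), `mean_freq_control`, `mean_freq_sorted`,
#'   `enrichment_score`, `log2_score`, `p_value`, `q_value`, `rank`.
#' @export
screen_enrichment <- function(counts, contrast = "max", pseudocount = 0.5) {
  counts <- as_tibble(counts)
  conds <- unique(counts$condition)
  if (!"control" %in% conds) abort("counts must include a 'control' condition")
  if (!contrast %in% conds) {
    abort(sprintf("contrast condition '%s' not present", contrast))
  }
  fr <- counts |>
    filter(.data$condition %in% c("control", contrast)) |>
    compute_frequency(pseudocount)
  per_gene <- fr |>
    group_by(.data$gene_id) |>
    summarise(
      freq_control = list(.data$freq[.data$condition == "control"]),
      freq_sorted = list(.data$freq[.data$condition == contrast]),
      .groups = "drop"
    ) |>
    mutate(
      mean_freq_control = purrr::map_dbl(.data$freq_control, mean),
      mean_freq_sorted = purrr::map_dbl(.data$freq_sorted, mean)
    )
  sc <- enrichment_score(per_gene$mean_freq_sorted,
                         per_gene$mean_freq_control)
  res <- bind_cols(per_gene, sc) |>
    mutate(
      p_value = purrr::map2_dbl(.data$freq_sorted, .data$freq_control,
                                test_enrichment),
      q_value = p.adjust(.data$p_value, method = "BH")
    )
  ord <- if (identical(contrast, "min")) {
    order(res$log2_score, res$gene_id)
  } else {
    order(-res$log2_score, res$gene_id)
  }
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  structure(res,
            contrast = contrast, pseudocount = pseudocount,
            class = c("enrichment_result", class(res)))
}

#' Shortlist top-ranked candidate genes
#'
#' Takes the head of an [screen_enrichment()] ranking (already directional:
#' most enriched first for `max`, most depleted first for `min`).
#'
#' @param results An `enrichment_result` (or a list of them for several
#'   contrasts).
#' @param top_n Number of candidates to keep per result; recycled over a
#'   list.
#' @return Candidate tibble(s) with a `direction` column.
#' @export
rank_candidates <- function(results, top_n = 10L) {
  pick <- function(res, k) {
    out <- slice_head(as_tibble(res), n = k)
    out$direction <- attr(res, "contrast")
    out
  }
  if (inherits(results, "enrichment_result")) {
    return(pick(results, top_n))
  }
  top_n <- rep_len(top_n, length(results))
  bind_rows(purrr::map2(results, top_n, pick))
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(x) |>
    select(-all_of(c("freq_control", "freq_sorted")))
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    contrast = attr(x, "contrast"),
    n_genes = nrow(x),
    n_replicates_control = length(x$freq_control[[1]]),
    n_replicates_sorted = length(x$freq_sorted[[1]]),
    n_sig_q05 = sum(x$q_value < 0.05),
    pseudocount = attr(x, "pseudocount")
  )
}
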