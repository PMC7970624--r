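.read_fastq_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("read_id", "seq") %in% names(x)))
    return(as_tibble(x))
  }
  dna <- Biostrings::readDNAStringSet(x, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(dna)),
         seq = unname(as.character(dna)))
}

#' Demultiplex barcoded reads into samples
#'
#' Each read is assigned to the unique sample whose barcode matches the
#' read start within `max_mismatch` edits, in either orientation (forward,
#' or barcode at the start of the reverse complement). Matching uses edit
#' distance on a short prefix window so barcode indels are tolerated;
#' assigned reads are returned oriented forward with the barcode-length
#' prefix trimmed. Reads matching no barcode, or more than one, are
#' reported unassigned.
#'
#' @param reads FASTQ path(s) or a tibble with `read_id`, `seq`.
#' @param sample_sheet Tibble with `sample`, `barcode` (and typically
#'   `condition`, `replicate`).
#' @param max_mismatch Maximum barcode edit distance (default 2). Barcodes
#'   must be pairwise more than `2 * max_mismatch` apart, else a
#'   configuration error is raised.
#' @return A tibble `read_id`, `sample`, `seq` (oriented, trimmed) for
#'   assigned reads; unassigned reads are attached as attribute
#'   `unassigned`.
#' @export
demultiplex <- function(reads, sample_sheet, max_mismatch = 2L) {
  reads <- if (is.character(reads)) {
    bind_rows(lapply(reads, .read_fastq_tbl))
  } else {
    .read_fastq_tbl(reads)
  }
  bc <- sample_sheet$barcode
  if (anyDuplicated(bc) > 0L) abort("duplicate barcodes in sample sheet")
  if (length(bc) > 1L) {
    pd <- adist(bc)
    if (min(pd[upper.tri(pd)]) <= 2L * max_mismatch) {
      abort(sprintf("barcode pair closer than 2 x max_mismatch = %d edits",
                    2L * max_mismatch),
            class = "crisprsort_barcode_collision")
    }
  }
  blen <- nchar(bc)
  win <- max(blen) + max_mismatch + 1L
  fwd_prefix <- substr(reads$seq, 1L, win)
  rev_seq <- revcomp(reads$seq)
  rev_prefix <- substr(rev_seq, 1L, win)
  d_fwd <- adist(bc, fwd_prefix, partial = TRUE)   # barcodes x reads
  d_rev <- adist(bc, rev_prefix, partial = TRUE)
  d <- pmin(d_fwd, d_rev)
  best <- apply(d, 2L, which.min)
  best_d <- d[cbind(best, seq_len(ncol(d)))]
  n_at_best <- colSums(d == rep(best_d, each = nrow(d)))
  ok <- best_d <= max_mismatch & n_at_best == 1L
  use_rev <- ok & d_rev[cbind(best, seq_len(ncol(d)))] <
    d_fwd[cbind(best, seq_len(ncol(d)))]
  oriented <- ifelse(use_rev, rev_seq, reads$seq)
  trimmed <- substr(oriented, blen[best] + 1L, nchar(oriented))
  out <- tibble(
    read_id = reads$read_id[ok],
    sample = sample_sheet$sample[best[ok]],
    seq = trimmed[ok]
  )
  attr(out, "unassigned") <- tibble(
    read_id = reads$read_id[!ok],
    reason = ifelse(n_at_best[!ok] > 1L & best_d[!ok] <= max_mismatch,
                    "ambiguous barcode", "no barcode within threshold")
  )
  out
}

#' Assign reads to library members by edit distance
#'
#' Each read is compared (Levenshtein distance, optionally in both
#' orientations) to every library member's reference sequence and assigned
#' to the member minimising the distance, provided the minimum is unique
#' and no larger than `max_edit_fraction` of that member's length.
#' Equidistant minima are ambiguous; distances above the threshold are
#' unassigned. The minimum pairwise distance between members is reported
#' as attribute `min_member_distance` (members must be distinguishable).
#'
#' @param reads Tibble with `read_id`, `seq` (e.g. from [demultiplex()]).
#' @param library Design tibble with `gene_id` and the reference column.
#' @param max_edit_fraction Assignment threshold as a fraction of member
#'   length (default 0.15, about three times the default simulated
#'   per-base error rate).
#' @param both_strands Compare against both orientations (default TRUE;
#'   set FALSE when reads were already oriented by demultiplexing).
#' @param ref_col Column of `library` holding the reference sequence
#'   (default `adaptored_seq`).
#' @return A tibble `read_id`, `gene_id` (`NA` unless assigned),
#'   `distance`, `status` in {assigned, ambiguous, unassigned}.
#' @export
assign_reads <- function(reads, library, max_edit_fraction = 0.15,
                         both_strands = TRUE, ref_col = "adaptored_seq") {
  library <- as_tibble(library)
  if (nrow(library) == 0L) abort("empty library")
  if (!ref_col %in% names(library)) {
    abort(sprintf("library has no '%s' column", ref_col))
  }
  refs <- library[[ref_col]]
  if (nrow(library) > 1L) {
    pd <- adist(refs)
    min_member <- min(pd[upper.tri(pd)])
  } else {
    min_member <- NA_integer_
  }
  if (nrow(reads) == 0L) {
    out <- tibble(read_id = character(), gene_id = character(),
                  distance = integer(), status = character())
    attr(out, "min_member_distance") <- min_member
    return(out)
  }
  d <- adist(reads$seq, refs)                       # reads x members
  if (both_strands) d <- pmin(d, adist(revcomp(reads$seq), refs))
  best_d <- apply(d, 1L, min)
  n_at_best <- rowSums(d == best_d)
  best <- max.col(-d, ties.method = "first")
  thr <- floor(max_edit_fraction * nchar(refs[best]))
  status <- ifelse(best_d > thr, "unassigned",
                   ifelse(n_at_best > 1L, "ambiguous", "assigned"))
  out <- tibble(
    read_id = reads$read_id,
    gene_id = ifelse(status == "assigned", library$gene_id[best],
                     NA_character_),
    distance = as.integer(best_d),
    status = status
  )
  attr(out, "min_member_distance") <- min_member
  out
}

#' Build a per-gene count table from read assignments
#'
#' Tallies assigned reads per sample and gene over the full library gene
#' set (zero-filled), recording per-sample assigned/ambiguous/unassigned
#' totals so that counts are conserved: assigned + ambiguous + unassigned
#' equals reads processed for every sample.
#'
#' @param assignments Tibble from [assign_reads()] with an added `sample`
#'   column (plus rows for demultiplex-unassigned reads if available).
#' @param library Design tibble (defines the gene set).
#' @param sample_sheet Tibble with `sample`, `condition`, `replicate`.
#' @return A long count tibble `sample`, `condition`, `replicate`,
#'   `gene_id`, `count` with attribute `sample_stats` (per-sample totals).
#' @export
count_table <- function(assignments, library, sample_sheet) {
  genes <- as_tibble(library)$gene_id
  grid <- tidyr::expand_grid(
    sample = sample_sheet$sample, gene_id = genes
  )
  tallies <- assignments |>
    filter(.data$status == "assigned") |>
    count(.data$sample, .data$gene_id, name = "count")
  counts <- grid |>
    left_join(tallies, by = c("sample", "gene_id")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    left_join(select(sample_sheet, all_of(c("sample", "condition",
                                            "replicate"))),
              by = "sample") |>
    select(all_of(c("sample", "condition", "replicate", "gene_id", "count")))
  stats <- assignments |>
    group_by(.data$sample) |>
    summarise(
      assigned = sum(.data$status == "assigned"),
      ambiguous = sum(.data$status == "ambiguous"),
      unassigned = sum(.data$status == "unassigned"),
      total = n(), .groups = "drop"
    )
  attr(counts, "sample_stats") <- stats
  counts
}

#' Quantify amplicon FASTQ files into a count table
#'
#' One-shot pipeline: demultiplex by barcode, assign reads to library
#' members by edit distance (single orientation — reads were oriented
#' during demultiplexing), and tally per-gene counts.
#'
#' @param fastq FASTQ path(s) or read tibble.
#' @param library Design tibble with `gene_id` and `adaptored_seq`.
#' @param sample_sheet Tibble with `sample`, `barcode`, `condition`,
#'   `replicate`.
#' @param max_barcode_mismatch Barcode edit threshold for [demultiplex()].
#' @param max_edit_fraction Assignment threshold for [assign_reads()].
#' @return A long count tibble, see [count_table()].
#' @export
quantify_reads <- function(fastq, library, sample_sheet,
                           max_barcode_mismatch = 2L,
                           max_edit_fraction = 0.15) {
  demuxed <- demultiplex(fastq, sample_sheet, max_barcode_mismatch)
  asn <- assign_reads(demuxed, library, max_edit_fraction,
                      both_strands = FALSE)
  asn$sample <- demuxed$sample
  count_table(asn, library, sample_sheet)
}

#' Gini coefficient of a non-negative vector
#'
#' Computed from the Lorenz curve of sorted values; 0 for perfectly uniform
#' representation.
#'
#' @param x Non-negative numeric vector.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_coefficient <- function(x) {
  stopifnot(all(x >= 0), length(x) > 0L)
  if (sum(x) == 0) return(0)
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Library representation QC for a single sample
#'
#' Summarises how evenly library members are represented in one pool:
#' extreme counts, fold-range, dropouts (members with zero reads), and the
#' Gini coefficient of the count distribution.
#'
#' @param counts Long count tibble (one sample, or use `sample` to pick
#'   one).
#' @param sample Optional sample name to filter on.
#' @return One-row tibble: `sample`, `n_members`, `min_count`, `max_count`,
#'   `fold_range` (`Inf` when a member is missing), `n_missing`, `missing`
#'   (list column of dropout gene ids), `gini`.
#' @export
library_uniformity <- function(counts, sample = NULL) {
  counts <- as_tibble(counts)
  if (!is.null(sample)) {
    smp <- sample
    counts <- filter(counts, .data$sample == smp)
  }
  if (length(unique(counts$sample)) > 1L) {
    abort("counts span multiple samples; pass `sample` to pick one")
  }
  x <- counts$count
  tibble(
    sample = counts$sample[1],
    n_members = length(x),
    min_count = min(x), max_count = max(x),
    fold_range = if (min(x) > 0) max(x) / min(x) else Inf,
    n_missing = sum(x == 0L),
    missing = list(counts$gene_id[x == 0L]),
    gini = gini_coefficient(x)
  )
}

#' Fold coverage of a library
#'
#' Number of clones (or reads) per library member.
#'
#' @param n_clones Total clones screened.
#' @param n_members Library size (> 0).
#' @return `n_clones / n_members`.
#' @examples
#' fold_coverage(257754, 361)  # 714
#' @export
fold_coverage <- function(n_clones, n_members) {
  if (any(n_members <= 0)) abort("n_members must be > 0")
  n_clones / n_members
}
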