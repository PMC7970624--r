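#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement over plain character vectors of A/C/G/T
#' (IUPAC ambiguity codes are accepted and complemented per Biostrings).
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp("ATGC")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

.check_acgt <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    abort(
      sprintf("%s contains non-ACGT characters (first offender: %s)",
              what, seq[which(bad)[1]]),
      class = "crisprsort_alphabet_error"
    )
  }
  invisible(seq)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation starts at the first base and stops silently at the last
#' complete codon, so frame-shifted sequences (length not a multiple of
#' three) are permitted; stop codons are rendered as `*`.
#'
#' @param seq Character vector of A/C/G/T sequences.
#' @return Character vector of amino-acid strings (possibly empty).
#' @examples
#' translate_dna("ATGTAA")  # "M*"
#' @export
translate_dna <- function(seq) {
  stopifnot(is.character(seq))
  .check_acgt(seq, "coding sequence")
  vapply(seq, function(s) {
    n <- 3L * (nchar(s) %/% 3L)
    if (n == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, n)),
      no.init.codon = TRUE
    ))
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of a sequence
#'
#' @param seq Non-empty character vector of A/C/G/T sequences.
#' @return Numeric vector of G+C fractions in `[0, 1]`.
#' @examples
#' gc_fraction("GGCC")  # 1
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq))
  if (any(!nzchar(seq))) abort("empty sequence", class = "crisprsort_empty_seq")
  .check_acgt(seq)
  gc <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq), "GC")
  as.numeric(gc) / nchar(seq)
}

#' Longest homopolymer run in a sequence
#'
#' @inheritParams gc_fraction
#' @return Integer vector: length of the longest run of one identical base.
#' @examples
#' max_homopolymer("AAAAT")  # 4
#' @export
max_homopolymer <- function(seq) {
  stopifnot(is.character(seq))
  if (any(!nzchar(seq))) abort("empty sequence", class = "crisprsort_empty_seq")
  .check_acgt(seq)
  vapply(strsplit(seq, "", fixed = TRUE),
         function(ch) max(rle(ch)$lengths), integer(1))
}

.read_contigs <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    out <- as.character(Biostrings::readDNAStringSet(x))
  } else if (is.character(x) && !is.null(names(x))) {
    out <- x
  } else {
    abort("contigs must be a FASTA path, a named character vector or a DNAStringSet")
  }
  # FASTA descriptions: keep the first whitespace-delimited token as the id
  names(out) <- sub("\\s.*$", "", names(out))
  toupper(out)
}

.validate_cds <- function(cds) {
  if (grepl("[^ACGT]", cds)) return("non-ACGT characters in CDS")
  if (nchar(cds) < 30L) return("CDS shorter than 30 nt")
  if (nchar(cds) %% 3L != 0L) return("CDS length not a multiple of 3")
  if (substr(cds, 1L, 3L) != "ATG") return("CDS does not start with ATG")
  aa <- translate_dna(cds)
  internal <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", internal, fixed = TRUE)) return("internal stop codon")
  NA_character_
}

#' Read target ORFs from a FASTA and an annotation table
#'
#' The FASTA supplies contig (or chromosome) sequences; the annotation TSV
#' supplies one row per gene with columns `gene_id`, `chrom`, `start`, `end`
#' (1-based inclusive), `strand` (`+`/`-`) and `essential` (logical). The
#' coding sequence is sliced from the contig and reverse-complemented for
#' minus-strand genes. Records violating the CDS invariants (ATG start,
#' length a multiple of three and at least 30 nt, no internal stop) are
#' returned flagged invalid with a reason rather than dropped; a gene whose
#' contig is missing from the FASTA is a hard error.
#'
#' @param fasta Path to a FASTA file, named character vector or DNAStringSet.
#' @param annotation Path to a TSV file or a data frame with the columns above.
#' @return A tibble with one row per annotation row: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `essential`, `cds_seq`, `valid`,
#'   `invalid_reason`.
#' @export
read_orfs <- function(fasta, annotation) {
  contigs <- .read_contigs(fasta)
  ann <- if (is.data.frame(annotation)) {
    as_tibble(annotation)
  } else {
    readr::read_tsv(annotation, show_col_types = FALSE)
  }
  need <- c("gene_id", "chrom", "start", "end", "strand", "essential")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) {
    abort(paste0("annotation is missing column(s): ", paste(miss, collapse = ", ")))
  }
  rows <- purrr::pmap(
    list(ann$gene_id, ann$chrom, ann$start, ann$end, ann$strand),
    function(gid, chrom, start, end, strand) {
      if (!chrom %in% names(contigs)) {
        abort(sprintf("no sequence for gene %s: contig '%s' absent from FASTA",
                      gid, chrom),
              class = "crisprsort_missing_sequence")
      }
      ctg <- contigs[[chrom]]
      if (start < 1L || end > nchar(ctg) || start > end) {
        abort(sprintf("gene %s: coordinates [%d, %d] outside contig '%s' (1..%d)",
                      gid, start, end, chrom, nchar(ctg)))
      }
      cds <- substr(ctg, start, end)
      if (identical(strand, "-")) cds <- revcomp(cds)
      tibble(cds_seq = cds, invalid_reason = .validate_cds(cds))
    }
  )
  out <- bind_cols(as_tibble(ann[need]), bind_rows(rows))
  out$essential <- as.logical(out$essential)
  out$valid <- is.na(out$invalid_reason)
  select(out, all_of(c("gene_id", "chrom", "start", "end", "strand",
                       "essential", "cds_seq", "valid", "invalid_reason")))
}

#' Derive the annotation table from a GFF3 file
#'
#' Convenience layer over the canonical TSV input: gene features are read
#' with rtracklayer and reshaped into the `read_orfs()` annotation columns.
#' Essentiality is taken from an `essential` attribute when present, else
#' `FALSE`.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `essential`.
#' @export
read_annotation_gff <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_annotation_gff() requires the rtracklayer package")
  }
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[as.character(gr$type) == feature_type, , drop = FALSE]
  ess <- if ("essential" %in% names(gr)) {
    tolower(as.character(gr$essential)) %in% c("true", "1", "yes")
  } else {
    rep(FALSE, nrow(gr))
  }
  id <- if ("ID" %in% names(gr)) as.character(gr$ID) else as.character(gr$Name)
  tibble(
    gene_id = id,
    chrom = as.character(gr$seqnames),
    start = gr$start,
    end = gr$end,
    strand = as.character(gr$strand),
    essential = ess
  )
}
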