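# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no binary fixtures.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random CDS: ATG + non-stop codons + TAA.
rand_cds <- function(n_nt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_nt %% 3 == 0, n_nt >= 9)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"))[, 3:1], 1, paste0,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste0(sample(sense, n_nt / 3 - 2, replace = TRUE),
                       collapse = ""), "TAA")
}

# Write a wrapped FASTA file (optionally with CRLF line endings).
write_fasta <- function(seqs, path, width = 60, crlf = FALSE) {
  eol <- if (crlf) "\r\n" else "\n"
  con <- file(path, "wb")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeChar(paste0(">", nm, eol), con, eos = NULL)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    for (st in starts) {
      writeChar(paste0(substr(s, st, st + width - 1), eol), con, eos = NULL)
    }
  }
  path
}

# Independent naive guide enumeration oracle: slide over both strands,
# collect every 20-mer 5' of an NGG.
oracle_enumerate <- function(cds) {
  hits <- list()
  scan <- function(s, strand) {
    n <- nchar(s)
    for (p in seq_len(max(0, n - 22))) {
      pam <- substr(s, p + 20, p + 22)
      if (substr(pam, 2, 3) == "GG") {
        hits[[length(hits) + 1]] <<- data.frame(
          protospacer = substr(s, p, p + 19), pam = pam, strand = strand
        )
      }
    }
  }
  scan(cds, "+")
  scan(crisprsort::revcomp(cds), "-")
  do.call(rbind, hits)
}

# Independent comparator oracle for guide selection (same published rules,
# separate code path): hard filters, tiered position preference, then max
# off-target mismatch, min cut site, lexicographic protospacer.
oracle_select <- function(cand, gc_max = 0.5, max_run = 3) {
  cand <- cand[cand$gc <= gc_max & cand$max_run <= max_run, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  for (bound in c(0.25, 0.5, 1.01)) {
    tier <- cand[cand$position_fraction < bound, , drop = FALSE]
    if (nrow(tier) == 0) next
    ot <- tier$offtarget_min_mismatch
    if (all(is.na(ot))) ot <- rep(0, nrow(tier))
    tier <- tier[order(-ot, tier$cut_site, tier$protospacer), , drop = FALSE]
    return(tier[1, ])
  }
  NULL
}
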