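#' Enumerate candidate guides within a coding sequence
#'
#' Scans both strands of the CDS for every protospacer immediately 5' of an
#' NGG PAM and annotates each with GC fraction, maximum homopolymer run,
#' cut-site position (0-based CDS offset of the blunt Cas9 cut, 3 bp from
#' the PAM), position fraction, and — when a [genome_index()] is supplied —
#' the minimum Hamming distance to any other PAM-adjacent 20-mer in the
#' genome. Windows overlapping ambiguity codes are disqualified.
#'
#' @param orf One ORF record: a one-row data frame (or list) with at least
#'   `gene_id` and `cds_seq`; genomic `chrom`/`start`/`end`/`strand` are used
#'   to exclude the candidate's own genomic site from off-target counting.
#' @param rules A [design_rules()] object.
#' @param genome Optional [genome_index()] for off-target annotation; when
#'   absent `offtarget_min_mismatch` is `NA` (criterion skipped and flagged).
#' @return A tibble of candidates: `gene_id`, `protospacer`, `pam`, `strand`
#'   (relative to the CDS), `span_start0` (0-based CDS start of the 23 nt
#'   protospacer+PAM span), `cut_site`, `position_fraction`, `gc`, `max_run`,
#'   `offtarget_min_mismatch`, `pass_gc`, `pass_run`, `pass_position`.
#' @export
enumerate_guides <- function(orf, rules = design_rules(), genome = NULL) {
  orf <- as.list(orf)
  s <- toupper(orf$cds_seq)
  n <- nchar(s)
  gl <- rules$guide_len
  span <- rules$replaced_span
  empty <- tibble(
    gene_id = character(), protospacer = character(), pam = character(),
    strand = character(), span_start0 = integer(), cut_site = integer(),
    position_fraction = double(), gc = double(), max_run = integer(),
    offtarget_min_mismatch = integer(), pass_gc = logical(),
    pass_run = logical(), pass_position = logical()
  )
  if (n < span) return(empty)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  # plus strand: span [p, p+22] 1-based, GG at [p+21, p+22]
  gg <- which(ch[-n] == "G" & ch[-1] == "G")
  p_plus <- gg - gl - 1L
  p_plus <- p_plus[p_plus >= 1L]
  cc <- which(ch[-n] == "C" & ch[-1] == "C")
  p_minus <- cc[cc + span - 1L <= n]          # span [c, c+22], CC at [c, c+1]
  plus <- if (length(p_plus) > 0L) tibble(
    gene_id = orf$gene_id,
    protospacer = substring(s, p_plus, p_plus + gl - 1L),
    pam = substring(s, p_plus + gl, p_plus + gl + 2L),
    strand = "+",
    span_start0 = p_plus - 1L,
    cut_site = p_plus - 1L + 17L
  ) else NULL
  minus <- if (length(p_minus) > 0L) tibble(
    gene_id = orf$gene_id,
    protospacer = revcomp(substring(s, p_minus + 3L, p_minus + span - 1L)),
    pam = revcomp(substring(s, p_minus, p_minus + 2L)),
    strand = "-",
    span_start0 = p_minus - 1L,
    cut_site = p_minus - 1L + 6L
  ) else NULL
  out <- bind_rows(plus, minus)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[!grepl("[^ACGT]", paste0(out$protospacer, out$pam)), , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out <- mutate(
    out,
    position_fraction = .data$cut_site / n,
    gc = gc_fraction(.data$protospacer),
    max_run = max_homopolymer(.data$protospacer)
  )
  out$offtarget_min_mismatch <- if (!is.null(genome)) {
    .offtarget_min_mismatch(genome, out$protospacer,
                            .candidate_site_keys(orf, out, n, gl))
  } else {
    rep(NA_integer_, nrow(out))
  }
  out <- mutate(
    out,
    pass_gc = .data$gc <= rules$gc_max,
    pass_run = .data$max_run <= rules$max_run,
    pass_position = .data$position_fraction < rules$position_fraction_max
  )
  arrange(out, .data$span_start0, .data$strand)
}

# Map each candidate's CDS-relative site to the genome_index key
# "contig:pos0:strand" so the candidate's own site is excluded from
# off-target counting. Returns NA keys when the ORF has no coordinates.
.candidate_site_keys <- function(orf, cand, cds_len, gl) {
  if (is.null(orf$chrom) || is.null(orf$start) || is.na(orf$chrom)) {
    return(rep(NA_character_, nrow(cand)))
  }
  g_start0 <- orf$start - 1L
  g_end0 <- orf$end - 1L
  on_plus_gene <- identical(orf$strand, "+") || is.null(orf$strand)
  keys <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p0 <- cand$span_start0[i]
    if (cand$strand[i] == "+") {
      # protospacer at CDS [p0, p0+19]
      if (on_plus_gene) {
        keys[i] <- paste(orf$chrom, g_start0 + p0, "+", sep = ":")
      } else {
        keys[i] <- paste(orf$chrom, g_end0 - (p0 + gl - 1L), "-", sep = ":")
      }
    } else {
      # 20-mer at CDS [p0+3, p0+22]
      if (on_plus_gene) {
        keys[i] <- paste(orf$chrom, g_start0 + p0 + 3L, "-", sep = ":")
      } else {
        keys[i] <- paste(orf$chrom, g_end0 - (p0 + gl + 2L), "+", sep = ":")
      }
    }
  }
  keys
}

# Order candidates for selection: fallback tier (first 1/4, first 1/2, whole
# CDS), hard filters applied, then maximal off-target mismatch, earliest cut
# site, lexicographically smallest protospacer.
.rank_guides <- function(candidates, rules) {
  ok <- filter(candidates, .data$pass_gc, .data$pass_run)
  if (nrow(ok) == 0L) return(ok)
  tier_bound <- c(rules$position_fraction_max, 0.5, 1.0)
  ok$fallback_tier <- vapply(ok$position_fraction, function(f) {
    which(f < tier_bound + c(0, 0, 1e-9))[1]
  }, integer(1))
  ot <- ifelse(is.na(ok$offtarget_min_mismatch), 0L, ok$offtarget_min_mismatch)
  ok[order(ok$fallback_tier, -ot, ok$cut_site, ok$protospacer), , drop = FALSE]
}

#' Select the guide for one gene
#'
#' Deterministic choice among candidates passing the hard GC and
#' homopolymer filters: candidates cutting in the first quarter of the CDS
#' are preferred; if none passes there the position constraint is relaxed to
#' the first half, then the whole CDS, and the tier used is recorded in
#' `fallback_tier` (1/2/3) with a warning for tiers above 1. Within a tier
#' the candidate with maximal off-target minimum mismatch wins; ties break
#' by smallest cut site, then lexicographically smallest protospacer.
#'
#' @param candidates Tibble from [enumerate_guides()].
#' @param rules A [design_rules()] object.
#' @return A one-row tibble (the chosen candidate) with `fallback_tier`.
#' @export
select_guide <- function(candidates, rules = design_rules()) {
  if (nrow(candidates) == 0L) {
    abort("no guide candidates: no PAM-adjacent site in the CDS",
          class = "crisprsort_undesignable")
  }
  ranked <- .rank_guides(candidates, rules)
  if (nrow(ranked) == 0L) {
    abort(
      sprintf(
        "gene %s undesignable: of %d candidates, %d fail GC <= %.0f%% and %d fail run <= %d",
        candidates$gene_id[1], nrow(candidates),
        sum(!candidates$pass_gc), 100 * rules$gc_max,
        sum(!candidates$pass_run), rules$max_run
      ),
      class = "crisprsort_undesignable"
    )
  }
  chosen <- ranked[1, , drop = FALSE]
  if (chosen$fallback_tier > 1L) {
    warn(sprintf("gene %s: no passing guide in the first quarter; fallback tier %d used",
                 chosen$gene_id, chosen$fallback_tier))
  }
  as_tibble(chosen)
}

# Build the 22 nt replacement for a 23 nt protospacer+PAM span, working in
# guide orientation: drop the base 5' of the PAM (protospacer position 20),
# flip the PAM GG to CC, then rewrite up to 4 seed bases (protospacer
# positions 15-19) minimally — fewest changes first, deterministic
# position/base order — until the edited CDS carries a stop codon within the
# replacement or 10 codons downstream AND the original site can no longer be
# re-cut. Returns NULL when no rewrite satisfies both.
.build_replacement <- function(cds, span_start0, guide_strand, protospacer,
                               pam, rules) {
  base_repl <- paste0(substr(protospacer, 1L, 19L), substr(pam, 1L, 1L), "CC")
  seed_pos <- 15:19
  try_one <- function(repl_guide) {
    repl_cds <- if (guide_strand == "-") revcomp(repl_guide) else repl_guide
    edited <- paste0(
      substr(cds, 1L, span_start0),
      repl_cds,
      substr(cds, span_start0 + rules$replaced_span + 1L, nchar(cds))
    )
    aa <- translate_dna(edited)
    stop_idx <- regexpr("*", aa, fixed = TRUE)[1]           # 1-based codon
    if (stop_idx < 0L) return(NULL)
    stop_nt0 <- (stop_idx - 1L) * 3L
    window_ok <- stop_nt0 <= span_start0 + rules$replacement_len + 30L
    if (!window_ok) return(NULL)
    if (.recut_possible(edited, protospacer)) return(NULL)
    list(repl_cds = repl_cds, edited = edited, ptc_codon_index = stop_idx - 1L)
  }
  res <- try_one(base_repl)
  if (!is.null(res)) return(res)
  bases <- c("A", "C", "G", "T")
  for (k in 1:4) {
    combos <- combn(seed_pos, k)
    for (ci in seq_len(ncol(combos))) {
      pos <- combos[, ci]
      orig <- substring(base_repl, pos, pos)
      opts <- lapply(orig, function(b) setdiff(bases, b))
      grid <- do.call(expand.grid,
                      c(opts, list(KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE)))
      for (gi in seq_len(nrow(grid))) {
        repl <- base_repl
        for (j in seq_along(pos)) {
          substr(repl, pos[j], pos[j]) <- grid[gi, j]
        }
        res <- try_one(repl)
        if (!is.null(res)) return(res)
      }
    }
  }
  NULL
}

# Can the original protospacer still be cut anywhere in the edited sequence?
# True when some NGG-adjacent 20-mer on either strand is within 2 mismatches
# of the protospacer.
.recut_possible <- function(seq, protospacer, max_mismatch = 2L) {
  gl <- nchar(protospacer)
  p_chars <- strsplit(protospacer, "", fixed = TRUE)[[1]]
  scan <- function(s) {
    n <- nchar(s)
    if (n < gl + 3L) return(FALSE)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    gg <- which(ch[-n] == "G" & ch[-1] == "G")
    starts <- gg - gl - 1L
    starts <- starts[starts >= 1L]
    for (p in starts) {
      mm <- sum(ch[p:(p + gl - 1L)] != p_chars)
      if (mm <= max_mismatch) return(TRUE)
    }
    FALSE
  }
  scan(seq) || scan(revcomp(seq))
}

#' Design the frameshift repair donor for a selected guide
#'
#' Constructs the 165 nt donor centred on the guide's 23 nt
#' protospacer+PAM span: a 71 nt left homology arm, a 22 nt replacement that
#' deletes one base (the frameshift), destroys the PAM and installs a
#' premature termination codon, and a 72 nt right arm. The donor is
#' validated in silico via [simulate_hdr_edit()] before return; designs
#' whose first stop codon falls at or beyond `rules$ptc_max_fraction` of the
#' original protein are rejected.
#'
#' @param orf One ORF record (one-row data frame or list with `gene_id`,
#'   `cds_seq`).
#' @param guide One guide row from [select_guide()] / [enumerate_guides()].
#' @param rules A [design_rules()] object.
#' @return One-row tibble: `gene_id`, `seq` (165 nt), `left_arm`,
#'   `replacement` (22 nt), `right_arm`, `span_start0`, `span_end0`
#'   (0-based half-open CDS span replaced), `ptc_codon_index` (0-based codon
#'   of the first stop in the edited CDS), `edited_protein_len` (residues
#'   before that stop), plus the guide's `protospacer`, `pam`, `strand`.
#' @export
design_frameshift_donor <- function(orf, guide, rules = design_rules()) {
  orf <- as.list(orf)
  guide <- as.list(guide)
  cds <- toupper(orf$cds_seq)
  n <- nchar(cds)
  p0 <- guide$span_start0
  if (p0 < rules$left_arm_len ||
      n - (p0 + rules$replaced_span) < rules$right_arm_len) {
    abort(
      sprintf(
        "gene %s: guide at CDS offset %d lacks %d/%d nt of context for the homology arms; choose another guide",
        orf$gene_id, p0, rules$left_arm_len, rules$right_arm_len
      ),
      class = "crisprsort_no_context"
    )
  }
  built <- .build_replacement(cds, p0, guide$strand, guide$protospacer,
                              guide$pam, rules)
  if (is.null(built)) {
    abort(sprintf("gene %s: no 22 nt replacement abolishes the cut site with an early stop",
                  orf$gene_id),
          class = "crisprsort_no_replacement")
  }
  orig_protein_len <- n %/% 3L - 1L   # codons excluding the (possible) stop
  if (built$ptc_codon_index >= rules$ptc_max_fraction * orig_protein_len) {
    abort(sprintf("gene %s: first stop at codon %d is beyond %.0f%% of the protein",
                  orf$gene_id, built$ptc_codon_index,
                  100 * rules$ptc_max_fraction),
          class = "crisprsort_ptc_late")
  }
  left <- substr(cds, p0 - rules$left_arm_len + 1L, p0)
  right <- substr(cds, p0 + rules$replaced_span + 1L,
                  p0 + rules$replaced_span + rules$right_arm_len)
  donor <- tibble(
    gene_id = orf$gene_id,
    seq = paste0(left, built$repl_cds, right),
    left_arm = left, replacement = built$repl_cds, right_arm = right,
    span_start0 = p0, span_end0 = p0 + rules$replaced_span,
    ptc_codon_index = built$ptc_codon_index,
    edited_protein_len = built$ptc_codon_index,
    protospacer = guide$protospacer, pam = guide$pam, strand = guide$strand
  )
  chk <- simulate_hdr_edit(cds, donor, protospacer = guide$protospacer)
  if (chk$report$frameshift_bp != 1L || isTRUE(chk$report$recut_possible)) {
    abort(sprintf("gene %s: donor failed in-silico HDR validation", orf$gene_id))
  }
  donor
}

#' Design the full-ORF deletion donor
#'
#' The alternative donor layout: 150 nt made of the 75 nt immediately
#' upstream and the 75 nt immediately downstream of the ORF, so
#' homology-directed repair removes the ORF completely.
#'
#' @param orf One ORF record with genomic `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`.
#' @param contigs Genome sequences (FASTA path, named character vector or
#'   DNAStringSet) containing `orf$chrom`.
#' @param rules A [design_rules()] object (`deletion_donor_len` is used).
#' @return One-row tibble: `gene_id`, `seq` (150 nt), `up_flank`,
#'   `down_flank` (genomic plus-strand orientation).
#' @export
design_deletion_donor <- function(orf, contigs, rules = design_rules()) {
  orf <- as.list(orf)
  contigs <- .read_contigs(contigs)
  flank <- rules$deletion_donor_len %/% 2L
  if (!orf$chrom %in% names(contigs)) {
    abort(sprintf("contig '%s' not found for gene %s", orf$chrom, orf$gene_id))
  }
  ctg <- contigs[[orf$chrom]]
  if (orf$start - flank < 1L || orf$end + flank > nchar(ctg)) {
    abort(sprintf("gene %s: fewer than %d nt of genomic context at a contig edge",
                  orf$gene_id, flank),
          class = "crisprsort_no_context")
  }
  up <- substr(ctg, orf$start - flank, orf$start - 1L)
  down <- substr(ctg, orf$end + 1L, orf$end + flank)
  tibble(gene_id = orf$gene_id, seq = paste0(up, down),
         up_flank = up, down_flank = down)
}

#' Apply an HDR donor to a locus in silico
#'
#' Locates the donor's two homology arms in the locus (each must occur
#' exactly once, left before right), splices the donor's replacement between
#' them, and reports the net length change, the first stop codon of the
#' edited sequence translated from `cds_start`, and whether the original
#' protospacer could still be cut (an NGG-adjacent 20-mer within 2
#' mismatches on either strand). Works for frameshift donors (`replacement`
#' of 22 nt) and deletion donors (`up_flank`/`down_flank` arms, empty
#' replacement).
#'
#' @param locus_seq Unedited locus (character scalar); for frameshift donors
#'   this is the CDS, so translation starts at base 1 by default.
#' @param donor One-row tibble/list with `left_arm`/`right_arm` (or
#'   `up_flank`/`down_flank`) and optionally `replacement` (default empty).
#' @param protospacer Optional original protospacer for the re-cut check;
#'   `recut_possible` is `NA` when absent.
#' @param cds_start 1-based position in the locus where translation starts.
#' @return A list: `edited` (the edited locus) and `report`, a one-row
#'   tibble with `net_length_change`, `frameshift_bp` (absolute change),
#'   `ptc_codon_index` (0-based, `NA` if no stop), `recut_possible`.
#' @export
simulate_hdr_edit <- function(locus_seq, donor, protospacer = NULL,
                              cds_start = 1L) {
  donor <- as.list(donor)
  left <- donor$left_arm %||% donor$up_flank
  right <- donor$right_arm %||% donor$down_flank
  repl <- donor$replacement %||% ""
  if (is.null(left) || is.null(right)) {
    abort("donor must carry left/right arms (or up/down flanks)")
  }
  locus <- toupper(locus_seq)
  find_once <- function(arm, label) {
    hits <- gregexpr(arm, locus, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      abort(sprintf("%s arm not found in locus (donor/locus mismatch)", label),
            class = "crisprsort_arm_error")
    }
    if (length(hits) > 1L) {
      abort(sprintf("%s arm found %d times in locus", label, length(hits)),
            class = "crisprsort_arm_error")
    }
    as.integer(hits[1])
  }
  lpos <- find_once(left, "left")
  rpos <- find_once(right, "right")
  lend <- lpos + nchar(left) - 1L
  if (rpos <= lend) {
    abort("right arm does not lie downstream of the left arm",
          class = "crisprsort_arm_error")
  }
  edited <- paste0(substr(locus, 1L, lend), repl,
                   substr(locus, rpos, nchar(locus)))
  net <- nchar(edited) - nchar(locus)
  tail_seq <- substr(edited, cds_start, nchar(edited))
  aa <- if (nchar(tail_seq) >= 3L && !grepl("[^ACGT]", tail_seq)) {
    translate_dna(tail_seq)
  } else {
    ""
  }
  stop_idx <- regexpr("*", aa, fixed = TRUE)[1]
  recut <- if (is.null(protospacer)) NA else .recut_possible(edited, protospacer)
  list(
    edited = edited,
    report = tibble(
      net_length_change = net,
      frameshift_bp = abs(net),
      ptc_codon_index = if (stop_idx > 0L) stop_idx - 1L else NA_integer_,
      recut_possible = recut
    )
  )
}

#' Assemble the synthesis fragment for one library member
#'
#' Core fragment = guide (20 nt) + sgRNA scaffold + terminator + donor
#' (165 nt); with the default parts this is 300 nt. The adaptored fragment
#' adds the 5' and 3' synthesis adaptors (43 nt combined).
#'
#' @param guide20 20 nt protospacer.
#' @param donor_seq 165 nt frameshift donor sequence.
#' @param parts Constant parts list, see [default_parts()].
#' @param rules A [design_rules()] object (length checks).
#' @return One-row tibble: `guide20`, `donor_seq`, `core_seq`,
#'   `adaptored_seq`, `core_len`, `adaptored_len`.
#' @export
assemble_fragment <- function(guide20, donor_seq, parts = default_parts(),
                              rules = design_rules()) {
  stopifnot(nchar(guide20) == rules$guide_len,
            nchar(donor_seq) == rules$donor_len)
  core_len <- rules$guide_len + nchar(parts$scaffold) +
    nchar(parts$terminator) + rules$donor_len
  if (core_len != rules$fragment_len) {
    abort(sprintf(
      "parts cannot reach fragment_len: %d (guide) + %d (scaffold) + %d (terminator) + %d (donor) = %d != %d",
      rules$guide_len, nchar(parts$scaffold), nchar(parts$terminator),
      rules$donor_len, core_len, rules$fragment_len))
  }
  ad_len <- nchar(parts$adaptor5) + nchar(parts$adaptor3)
  if (ad_len != rules$adaptor_len_total) {
    abort(sprintf("adaptor lengths %d + %d != %d",
                  nchar(parts$adaptor5), nchar(parts$adaptor3),
                  rules$adaptor_len_total))
  }
  core <- paste0(guide20, parts$scaffold, parts$terminator, donor_seq)
  tibble(
    guide20 = guide20, donor_seq = donor_seq, core_seq = core,
    adaptored_seq = paste0(parts$adaptor5, core, parts$adaptor3),
    core_len = nchar(core), adaptored_len = nchar(core) + ad_len
  )
}

#' Re-parse a core fragment into guide and donor
#'
#' Inverse of [assemble_fragment()]: verifies the constant scaffold and
#' terminator and returns the variable parts.
#'
#' @param core_seq Core fragment sequence.
#' @param parts Constant parts list used at assembly.
#' @param rules A [design_rules()] object.
#' @return A list with `guide20` and `donor_seq`.
#' @export
parse_fragment <- function(core_seq, parts = default_parts(),
                           rules = design_rules()) {
  gl <- rules$guide_len
  const <- paste0(parts$scaffold, parts$terminator)
  got <- substr(core_seq, gl + 1L, gl + nchar(const))
  if (got != const) {
    abort("core fragment does not contain the expected scaffold+terminator")
  }
  list(
    guide20 = substr(core_seq, 1L, gl),
    donor_seq = substr(core_seq, gl + nchar(const) + 1L, nchar(core_seq))
  )
}

#' Design the disruption library for a target set
#'
#' Runs the full per-gene design over every valid non-essential ORF: guide
#' enumeration, ranked selection (hard GC/homopolymer filters, first-quarter
#' preference with recorded fallback tiers, off-target maximisation when a
#' genome index is supplied), frameshift-donor construction with in-silico
#' HDR validation, and synthesis-fragment assembly. Genes for which every
#' candidate fails are reported, not dropped silently. The result is a pure
#' function of its inputs: re-running yields byte-identical output.
#'
#' @param orfs ORF tibble from [read_orfs()] (or [simulate_orfs()]).
#' @param rules A [design_rules()] object.
#' @param genome Optional [genome_index()].
#' @param parts Constant parts, see [default_parts()].
#' @return A tibble of class `design_library`, one row per designed gene,
#'   with guide, donor, fragment columns and `fallback_tier`; the QC report
#'   (undesignable genes with reasons, per-criterion pass rates, tier
#'   usage) is attached as attribute `qc`, see [design_qc()].
#' @export
design_library <- function(orfs, rules = design_rules(), genome = NULL,
                           parts = default_parts()) {
  orfs <- as_tibble(orfs)
  if (!"valid" %in% names(orfs)) orfs$valid <- TRUE
  targets <- filter(orfs, !.data$essential, .data$valid)
  excluded <- filter(orfs, .data$essential | !.data$valid)
  designs <- list()
  failures <- list()
  stats <- list()
  for (i in seq_len(nrow(targets))) {
    orf <- targets[i, ]
    cand <- enumerate_guides(orf, rules, genome)
    stats[[i]] <- tibble(
      gene_id = orf$gene_id, n_candidates = nrow(cand),
      n_pass_gc = sum(cand$pass_gc), n_pass_run = sum(cand$pass_run),
      n_pass_position = sum(cand$pass_position)
    )
    ranked <- if (nrow(cand) > 0L) .rank_guides(cand, rules) else cand
    if (nrow(ranked) == 0L) {
      failures[[length(failures) + 1L]] <- tibble(
        gene_id = orf$gene_id,
        reason = if (nrow(cand) == 0L) "no PAM-adjacent site" else
          "all candidates fail hard GC/homopolymer filters"
      )
      next
    }
    done <- FALSE
    last_err <- NULL
    for (j in seq_len(nrow(ranked))) {
      guide <- ranked[j, ]
      donor <- tryCatch(
        design_frameshift_donor(orf, guide, rules),
        crisprsort_no_context = function(e) e,
        crisprsort_no_replacement = function(e) e,
        crisprsort_ptc_late = function(e) e
      )
      if (inherits(donor, "condition")) {
        last_err <- conditionMessage(donor)
        next
      }
      frag <- assemble_fragment(guide$protospacer, donor$seq, parts, rules)
      designs[[length(designs) + 1L]] <- bind_cols(
        tibble(gene_id = orf$gene_id),
        select(guide, -"gene_id"),
        select(donor, all_of(c("seq", "left_arm", "replacement", "right_arm",
                               "ptc_codon_index", "edited_protein_len"))) |>
          dplyr::rename(donor_seq = "seq"),
        select(frag, all_of(c("core_seq", "adaptored_seq"))),
        tibble(n_guides_tried = j)
      )
      done <- TRUE
      break
    }
    if (!done) {
      failures[[length(failures) + 1L]] <- tibble(
        gene_id = orf$gene_id,
        reason = paste0("no candidate yields a valid donor (last: ",
                        last_err %||% "none tried", ")")
      )
    }
  }
  lib <- if (length(designs) > 0L) bind_rows(designs) else tibble()
  qc <- list(
    n_targets = nrow(targets),
    n_designed = length(designs),
    excluded = select(excluded, all_of(c("gene_id", "essential"))) |>
      mutate(reason = ifelse(.data$essential, "essential", "invalid CDS")),
    undesignable = if (length(failures) > 0L) bind_rows(failures) else
      tibble(gene_id = character(), reason = character()),
    candidate_stats = bind_rows(stats),
    tier_usage = if (length(designs) > 0L)
      count(lib, .data$fallback_tier) else tibble()
  )
  structure(lib, qc = qc, class = c("design_library", class(lib)))
}

#' QC report of a designed library
#'
#' @param library A [design_library()] result.
#' @return The QC list: target/designed counts, undesignable genes with
#'   reasons, per-gene candidate pass statistics and fallback-tier usage.
#' @export
design_qc <- function(library) {
  attr(library, "qc")
}

#' Partition a library into sub-pools with an equimolar mixing manifest
#'
#' Members are grouped by a class label (e.g. transporter family) into
#' pools; within each pool every member receives an equal mixing fraction.
#'
#' @param library Design tibble with `gene_id` and the class column.
#' @param class_column Name of the class label column.
#' @param scheme Optional named character vector mapping class label to pool
#'   name; by default each class is its own pool. A class absent from the
#'   scheme is an error.
#' @return A list: `members` (gene_id, class, pool, mix_fraction) and
#'   `manifest` (pool, n_members, member fraction; fractions sum to 1 per
#'   pool).
#' @export
partition_sublibraries <- function(library, class_column = "class",
                                   scheme = NULL) {
  library <- as_tibble(library)
  if (!class_column %in% names(library)) {
    abort(sprintf("class column '%s' not found", class_column))
  }
  cls <- as.character(library[[class_column]])
  if (anyNA(cls)) abort("every member needs a class label")
  if (is.null(scheme)) {
    pool <- cls
  } else {
    unknown <- setdiff(unique(cls), names(scheme))
    if (length(unknown) > 0L) {
      abort(paste0("unknown class label(s): ", paste(unknown, collapse = ", ")))
    }
    pool <- unname(scheme[cls])
  }
  members <- tibble(gene_id = library$gene_id, class = cls, pool = pool) |>
    group_by(.data$pool) |>
    mutate(mix_fraction = 1 / n()) |>
    ungroup()
  manifest <- members |>
    group_by(.data$pool) |>
    summarise(n_members = n(), member_fraction = 1 / n(),
              total_fraction = sum(.data$mix_fraction), .groups = "drop")
  list(members = members, manifest = manifest)
}
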