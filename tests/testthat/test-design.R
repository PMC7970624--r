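toy_orf <- function(n_nt = 600, seed = 5, gene_id = "toy") {
  tibble::tibble(
    gene_id = gene_id, chrom = NA_character_, start = NA_integer_,
    end = NA_integer_, strand = "+", essential = FALSE,
    cds_seq = rand_cds(n_nt, seed = seed), valid = TRUE,
    invalid_reason = NA_character_
  )
}

test_that("guide enumeration matches an exhaustive sliding-window oracle", {
  orf <- toy_orf(120, seed = 31)
  cand <- enumerate_guides(orf)
  ora <- oracle_enumerate(orf$cds_seq)
  expect_equal(nrow(cand), nrow(ora))
  key <- function(d) sort(paste(d$protospacer, d$pam, d$strand))
  expect_equal(key(cand), key(ora))
  # annotations recompute
  expect_equal(cand$gc, gc_fraction(cand$protospacer))
  expect_equal(cand$max_run, max_homopolymer(cand$protospacer))
  expect_true(all(cand$position_fraction >= 0 & cand$position_fraction < 1))
  # protospacer+PAM occurs at the recorded span on the recorded strand
  span <- substr(rep(orf$cds_seq, nrow(cand)), cand$span_start0 + 1,
                 cand$span_start0 + 23)
  expected <- ifelse(cand$strand == "+", paste0(cand$protospacer, cand$pam),
                     revcomp(paste0(cand$protospacer, cand$pam)))
  expect_equal(span, expected)
})

test_that("a CDS without GG or CC dinucleotides yields no candidates", {
  # alternating purine/pyrimidine pattern: no GG, no CC anywhere
  cds <- paste0(rep("GA", 40), collapse = "")
  orf <- toy_orf(); orf$cds_seq <- cds
  expect_equal(nrow(enumerate_guides(orf)), 0)
})

test_that("GC and run pass flags follow the hard-filter bounds", {
  orf <- toy_orf(300, seed = 33)
  cand <- enumerate_guides(orf)
  expect_equal(cand$pass_gc, cand$gc <= 0.5)
  expect_equal(cand$pass_run, cand$max_run <= 3L)
  over <- cand[cand$gc > 0.5, ]
  if (nrow(over) > 0) expect_false(any(over$pass_gc))
})

test_that("guide selection breaks ties by position and falls back in tiers", {
  base <- tibble::tibble(
    gene_id = "g", pam = "AGG", strand = "+",
    gc = 0.4, max_run = 2L, offtarget_min_mismatch = 5L,
    pass_gc = TRUE, pass_run = TRUE
  )
  two <- dplyr::bind_rows(base, base)
  two$protospacer <- c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA")
  two$span_start0 <- c(43L, 103L)
  two$cut_site <- c(60L, 120L)
  two$position_fraction <- c(0.10, 0.20)
  two$pass_position <- TRUE
  sel <- select_guide(two, design_rules())
  expect_equal(sel$position_fraction, 0.10)
  expect_equal(sel$fallback_tier, 1L)
  # all first-quarter candidates fail the run filter -> fallback to tier 2
  two$max_run <- c(4L, 2L)
  two$pass_run <- c(FALSE, TRUE)
  two$position_fraction <- c(0.10, 0.40)
  expect_warning(sel2 <- select_guide(two, design_rules()), "fallback tier 2")
  expect_equal(sel2$position_fraction, 0.40)
  expect_equal(sel2$fallback_tier, 2L)
  # nothing passes even relaxed -> undesignable with criteria listed
  two$pass_run <- FALSE
  expect_error(select_guide(two, design_rules()),
               class = "crisprsort_undesignable")
})

test_that("selection agrees with an independent comparator oracle", {
  orfs <- simulate_orfs(50, 600, seed = 77)
  gi <- genome_index(attr(orfs, "contigs"))
  rules <- design_rules()
  for (i in seq_len(nrow(orfs))) {
    cand <- enumerate_guides(orfs[i, ], rules, gi)
    ora <- oracle_select(as.data.frame(cand))
    if (is.null(ora)) {
      expect_error(select_guide(cand, rules),
                   class = "crisprsort_undesignable")
    } else {
      sel <- suppressWarnings(select_guide(cand, rules))
      expect_equal(sel$protospacer, ora$protospacer)
      expect_true(sel$gc <= 0.5)
      expect_true(sel$max_run <= 3L)
    }
  }
})

test_that("frameshift donors have the published arithmetic", {
  orf <- toy_orf(600, seed = 5)
  cand <- enumerate_guides(orf)
  lib <- design_library(orf)
  expect_equal(nrow(lib), 1)
  expect_equal(nchar(lib$donor_seq), 165L)
  expect_equal(nchar(lib$replacement), 22L)
  expect_equal(nchar(lib$left_arm), 71L)
  expect_equal(nchar(lib$right_arm), 72L)
  expect_equal(lib$donor_seq,
               paste0(lib$left_arm, lib$replacement, lib$right_arm))
  # arms are exact substrings of the unedited CDS
  expect_true(grepl(lib$left_arm, orf$cds_seq, fixed = TRUE))
  expect_true(grepl(lib$right_arm, orf$cds_seq, fixed = TRUE))
})

test_that("applying a frameshift donor shortens the locus by exactly 1 nt", {
  orf <- toy_orf(600, seed = 6)
  lib <- design_library(orf)
  donor <- list(left_arm = lib$left_arm, replacement = lib$replacement,
                right_arm = lib$right_arm)
  ed <- simulate_hdr_edit(orf$cds_seq, donor, protospacer = lib$protospacer)
  expect_equal(nchar(orf$cds_seq) - nchar(ed$edited), 1L)
  expect_equal(ed$report$frameshift_bp, 1L)
  expect_false(ed$report$recut_possible)
})

test_that("the PTC lands where hand-translation of the shifted frame says", {
  orf <- toy_orf(300, seed = 41)
  lib <- design_library(orf)
  ed <- simulate_hdr_edit(orf$cds_seq,
                          list(left_arm = lib$left_arm,
                               replacement = lib$replacement,
                               right_arm = lib$right_arm))
  # manual translation oracle: walk codons of the edited CDS to the stop
  edited <- ed$edited
  codons <- substring(edited, seq(1, nchar(edited) - 2, 3),
                      seq(3, nchar(edited), 3))
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  expect_equal(lib$ptc_codon_index, stops[1] - 1L)
  expect_equal(ed$report$ptc_codon_index, stops[1] - 1L)
  # the truncation is premature: before half of the original protein
  expect_lt(lib$ptc_codon_index, 0.5 * (nchar(orf$cds_seq) / 3 - 1))
})

test_that("every emitted donor passes frameshift/recut/PTC invariants", {
  orfs <- simulate_orfs(20, 600, seed = 55)
  lib <- design_library(orfs)
  for (i in seq_len(nrow(lib))) {
    orf <- orfs[orfs$gene_id == lib$gene_id[i], ]
    ed <- simulate_hdr_edit(orf$cds_seq,
                            list(left_arm = lib$left_arm[i],
                                 replacement = lib$replacement[i],
                                 right_arm = lib$right_arm[i]),
                            protospacer = lib$protospacer[i])
    expect_equal(ed$report$frameshift_bp, 1L)
    expect_false(ed$report$recut_possible)
    expect_lt(ed$report$ptc_codon_index,
              0.5 * (nchar(orf$cds_seq) / 3 - 1))
    expect_true(lib$gc[i] <= 0.5 && lib$max_run[i] <= 3L)
  }
})

test_that("hdr edits match a string-splice oracle on randomized donors", {
  set.seed(66)
  for (i in 1:50) {
    locus <- rand_dna(sample(200:400, 1))
    a <- sample(20:60, 1); la <- sample(20:40, 1)
    b <- a + la + sample(10:30, 1); lb <- sample(20:40, 1)
    if (b + lb - 1 > nchar(locus)) next
    left <- substr(locus, a, a + la - 1)
    right <- substr(locus, b, b + lb - 1)
    # arms must be unique in the locus for the donor to be applicable
    if (length(gregexpr(left, locus, fixed = TRUE)[[1]]) != 1) next
    if (length(gregexpr(right, locus, fixed = TRUE)[[1]]) != 1) next
    repl <- rand_dna(sample(0:25, 1))
    ed <- simulate_hdr_edit(locus, list(left_arm = left, right_arm = right,
                                        replacement = repl))
    oracle <- paste0(substr(locus, 1, a + la - 1), repl,
                     substr(locus, b, nchar(locus)))
    expect_equal(ed$edited, oracle)
    expect_equal(ed$report$net_length_change,
                 nchar(repl) - (b - (a + la)))
  }
})

test_that("identity donors leave the locus untouched", {
  locus <- rand_cds(300, seed = 68)
  left <- substr(locus, 50, 120)
  mid <- substr(locus, 121, 143)
  right <- substr(locus, 144, 215)
  ed <- simulate_hdr_edit(locus, list(left_arm = left, replacement = mid,
                                      right_arm = right))
  expect_equal(ed$edited, locus)
  expect_equal(ed$report$frameshift_bp, 0L)
})

test_that("mismatched or repeated arms are rejected", {
  locus <- paste0(rand_dna(100, seed = 70), rand_dna(0))
  expect_error(
    simulate_hdr_edit(locus, list(left_arm = "AAAAAAAAAAAAAAAAAAAAAAAAA",
                                  right_arm = substr(locus, 60, 90))),
    class = "crisprsort_arm_error"
  )
  dup <- paste0(locus, locus)
  expect_error(
    simulate_hdr_edit(dup, list(left_arm = substr(locus, 1, 30),
                                right_arm = substr(locus, 60, 90))),
    class = "crisprsort_arm_error"
  )
})

test_that("deletion donors remove the ORF exactly", {
  orfs <- simulate_orfs(3, 300, flank = 200, seed = 81)
  contigs <- attr(orfs, "contigs")
  for (i in 1:3) {
    dd <- design_deletion_donor(orfs[i, ], contigs)
    expect_equal(nchar(dd$seq), 150L)
    expect_equal(nchar(dd$up_flank), 75L)
    expect_equal(nchar(dd$down_flank), 75L)
    ctg <- contigs[[orfs$chrom[i]]]
    ed <- simulate_hdr_edit(ctg, dd)
    expect_equal(nchar(ctg) - nchar(ed$edited), nchar(orfs$cds_seq[i]))
    # flanks are adjacent in the edited contig
    expect_true(grepl(paste0(dd$up_flank, dd$down_flank), ed$edited,
                      fixed = TRUE))
  }
  # contig edge: not enough context
  short <- orfs[1, ]; short$start <- 10L; short$end <- 10L + 299L
  expect_error(design_deletion_donor(short, contigs),
               class = "crisprsort_no_context")
})

test_that("fragment assembly hits 300 nt core plus 43 nt of adaptors", {
  orf <- toy_orf(600, seed = 5)
  lib <- design_library(orf)
  frag <- assemble_fragment(lib$protospacer, lib$donor_seq)
  expect_equal(frag$core_len, 300L)
  expect_equal(frag$adaptored_len - frag$core_len, 43L)
  # round trip through the parser recovers guide and donor exactly
  parts <- parse_fragment(frag$core_seq)
  expect_equal(parts$guide20, lib$protospacer)
  expect_equal(parts$donor_seq, lib$donor_seq)
  # incompatible parts error with the arithmetic spelled out
  bad <- default_parts(); bad$scaffold <- substr(bad$scaffold, 1, 50)
  expect_error(assemble_fragment(lib$protospacer, lib$donor_seq, bad),
               "fragment_len")
})

test_that("library design is deterministic and honours essentiality", {
  orfs <- simulate_orfs(12, 600, seed = 91,
                        essential = rep(c(FALSE, TRUE), c(9, 3)))
  lib1 <- design_library(orfs)
  lib2 <- design_library(orfs)
  expect_identical(as.data.frame(lib1), as.data.frame(lib2))
  expect_true(all(lib1$gene_id %in% orfs$gene_id[!orfs$essential]))
  qc <- design_qc(lib1)
  expect_equal(qc$n_targets, 9)
  expect_equal(qc$n_designed + nrow(qc$undesignable), qc$n_targets)
  # all-essential input: empty library, non-empty report
  empty <- design_library(orfs[orfs$essential, ])
  expect_equal(nrow(empty), 0)
  eqc <- design_qc(empty)
  expect_equal(eqc$n_targets, 0)
  expect_equal(nrow(eqc$excluded), 3)
})

test_that("sub-library partitioning reproduces the five-pool layout", {
  sizes <- c(AD = 73, SeTS_A = 79, SeTS_B = 65, SeTS_C = 84, other = 60)
  lib <- tibble::tibble(
    gene_id = sprintf("m%03d", seq_len(sum(sizes))),
    class = rep(names(sizes), sizes)
  )
  part <- partition_sublibraries(lib, "class")
  expect_equal(nrow(part$manifest), 5)
  got <- setNames(part$manifest$n_members, part$manifest$pool)
  expect_equal(got[names(sizes)], sizes)
  # equimolar fractions sum to 1 within each pool
  sums <- tapply(part$members$mix_fraction, part$members$pool, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # single class -> one pool with everything
  one <- partition_sublibraries(transform(lib, class = "all"), "class")
  expect_equal(nrow(one$manifest), 1)
  expect_equal(one$manifest$n_members, sum(sizes))
  # unknown class label under a scheme is an error
  expect_error(
    partition_sublibraries(lib, "class", scheme = c(AD = "pool1")),
    "unknown class"
  )
})
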