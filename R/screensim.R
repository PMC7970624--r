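#' Simulate a target set of coding sequences
#'
#' Generates random ORFs that satisfy the CDS invariants: ATG start, random
#' non-stop codons, terminal TAA, no internal stop. Each ORF is laid out on
#' its own contig so the set doubles as a miniature genome for off-target
#' scanning and deletion-donor design; `flank` nt of random intergenic
#' sequence surround each CDS.
#'
#' @param n Number of ORFs.
#' @param cds_length CDS length in nt (multiple of 3, >= 30); recycled.
#' @param flank Intergenic context on each side of the CDS.
#' @param essential Logical vector (recycled) flagging essential genes.
#' @param seed Random seed (mandatory; design inputs must be reproducible).
#' @return A tibble in [read_orfs()] layout (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `essential`, `cds_seq`, `valid`, `invalid_reason`)
#'   with the contig sequences attached as attribute `contigs` (named
#'   character vector).
#' @export
simulate_orfs <- function(n, cds_length = 900L, flank = 200L,
                          essential = FALSE, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(all(cds_length %% 3L == 0L), all(cds_length >= 30L))
  cds_length <- rep_len(as.integer(cds_length), n)
  essential <- rep_len(as.logical(essential), n)
  set.seed(seed)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"))[, 3:1], 1, paste0,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n)
  contigs <- character(n)
  for (i in seq_len(n)) {
    n_codon <- cds_length[i] %/% 3L
    cds <- paste0("ATG",
                  paste0(sample(sense, n_codon - 2L, replace = TRUE),
                         collapse = ""),
                  "TAA")
    up <- paste0(sample(bases, flank, replace = TRUE), collapse = "")
    down <- paste0(sample(bases, flank, replace = TRUE), collapse = "")
    strand <- sample(c("+", "-"), 1L)
    placed <- if (strand == "-") revcomp(cds) else cds
    contigs[i] <- paste0(up, placed, down)
    rows[[i]] <- tibble(
      gene_id = sprintf("g%04d", i), chrom = sprintf("ctg%04d", i),
      start = flank + 1L, end = flank + cds_length[i], strand = strand,
      essential = essential[i], cds_seq = cds,
      valid = TRUE, invalid_reason = NA_character_
    )
  }
  names(contigs) <- sprintf("ctg%04d", seq_len(n))
  out <- bind_rows(rows)
  attr(out, "contigs") <- contigs
  out
}

#' Generate a barcode set with a guaranteed minimum pairwise distance
#'
#' @param n Number of barcodes.
#' @param width Barcode length in nt.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed Random seed.
#' @return Character vector of `n` barcodes.
#' @export
make_barcodes <- function(n, width = 16L, min_dist = 8L, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 10000L) abort("cannot satisfy the barcode distance constraint")
    cand <- paste0(sample(bases, width, replace = TRUE), collapse = "")
    if (max_homopolymer(cand) > 3L) next
    if (length(out) == 0L ||
        min(vapply(out, .hamming, integer(1), y = cand)) >= min_dist) {
      out <- c(out, cand)
    }
  }
  out
}

.hamming <- function(x, y) {
  sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
}

#' Configuration of a simulated sort-seq screen
#'
#' Defaults emulate the screen's study conditions: a skewed plasmid/cell
#' pool (log-normal member abundances), condition-specific fold-change
#' spikes in the FACS-sorted pools, three replicates per condition, and
#' long-read-style i.i.d. per-base errors (5% substitution, 3% insertion,
#' 3% deletion).
#'
#' @param n_reads Reads per sample.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters;
#'   `abundance_sdlog = 0` degenerates to uniform membership.
#' @param spikes Named list keyed by sorted condition (e.g. `max`, `min`),
#'   each a named numeric vector `gene_id -> fold change` relative to
#'   control (must be > 0); or a single named vector applied to every
#'   sorted condition.
#' @param conditions Character vector of conditions; must include
#'   `"control"`.
#' @param n_replicates Replicates per condition.
#' @param sub_rate,ins_rate,del_rate Per-base error rates in `[0, 1)`.
#' @param barcodes Barcode set (one per sample); generated via
#'   [make_barcodes()] when `NULL`.
#' @param seed Random seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 10000L, abundance_meanlog = 0,
                       abundance_sdlog = 1, spikes = list(),
                       conditions = c("control", "max", "min"),
                       n_replicates = 3L, sub_rate = 0.05, ins_rate = 0.03,
                       del_rate = 0.03, barcodes = NULL, seed) {
  if (missing(seed)) abort("seed is mandatory")
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates >= 1)) abort("error rates must lie in [0, 1)")
  if (!"control" %in% conditions) abort("conditions must include 'control'")
  if (is.numeric(spikes)) {
    spikes <- setNames(
      rep(list(spikes), length(setdiff(conditions, "control"))),
      setdiff(conditions, "control")
    )
  }
  if (any(unlist(spikes) <= 0)) abort("fold changes must be > 0")
  n_samples <- length(conditions) * n_replicates
  if (is.null(barcodes)) {
    barcodes <- make_barcodes(n_samples, seed = seed + 7L)
  }
  if (length(barcodes) < n_samples) {
    abort(sprintf("%d barcodes supplied for %d samples",
                  length(barcodes), n_samples))
  }
  structure(
    list(n_reads = as.integer(n_reads), abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog, spikes = spikes,
         conditions = conditions, n_replicates = as.integer(n_replicates),
         sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
         barcodes = barcodes, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.sample_grid <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = config$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$condition, config$conditions),
                     grid$replicate), ]
  tibble(
    sample = paste0(grid$condition, "_", grid$replicate),
    condition = grid$condition, replicate = grid$replicate,
    barcode = config$barcodes[seq_len(nrow(grid))]
  )
}

#' Simulate per-sample member probabilities
#'
#' One log-normal draw defines the true composition of the pool; sorted
#' samples multiply it by the configured fold-change spikes and
#' renormalise. Replicates of a condition share the same true probability
#' vector (they are draws from the same pool); replicate-to-replicate
#' variation enters through independent read sampling in
#' [simulate_reads()].
#'
#' @param library Design tibble (or anything with a `gene_id` column).
#' @param config A [sim_config()].
#' @return A long tibble: `sample`, `condition`, `replicate`, `barcode`,
#'   `gene_id`, `prob`; probabilities sum to 1 within each sample.
#' @export
simulate_abundances <- function(library, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- as_tibble(library)$gene_id
  if (length(genes) == 0L) abort("library is empty")
  set.seed(config$seed)
  base <- if (config$abundance_sdlog == 0) {
    rep(exp(config$abundance_meanlog), length(genes))
  } else {
    rlnorm(length(genes), config$abundance_meanlog, config$abundance_sdlog)
  }
  grid <- .sample_grid(config)
  purrr::pmap(grid, function(sample, condition, replicate, barcode) {
    fold <- rep(1, length(genes))
    sp <- config$spikes[[condition]]
    if (!is.null(sp)) {
      idx <- match(names(sp), genes)
      if (anyNA(idx)) {
        abort(paste0("spiked gene(s) not in library: ",
                     paste(names(sp)[is.na(idx)], collapse = ", ")))
      }
      fold[idx] <- sp
    }
    w <- base * fold
    tibble(sample = sample, condition = condition, replicate = replicate,
           barcode = barcode, gene_id = genes, prob = w / sum(w))
  }) |> bind_rows()
}

# i.i.d. per-base corruption: deletion, then substitution of survivors (to a
# different base), then insertion of a random base after each surviving
# position. Rates are per original base.
.corrupt_seq <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    keep <- runif(n) >= del_rate
    sub <- runif(n) < sub_rate
    for (i in which(sub & keep)) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    ins <- runif(n) < ins_rate
    emitted <- ifelse(keep, ch, "")
    if (any(ins)) {
      emitted[ins] <- paste0(emitted[ins],
                             sample(bases, sum(ins), replace = TRUE))
    }
    paste0(emitted, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate barcoded amplicon reads for every sample
#'
#' For each sample, members are drawn by their simulated probabilities;
#' each read is the sample barcode followed by the member's adaptored
#' synthesis fragment, reverse-complemented with probability 1/2 and
#' corrupted by i.i.d. per-base substitution/insertion/deletion errors.
#' Reads are written as FASTQ (Sanger encoding, constant placeholder
#' quality `I`) with a truth table mapping every read to its true member.
#' Fully reproducible from the config seed.
#'
#' @param library Design tibble with `gene_id` and `adaptored_seq`.
#' @param abundances Output of [simulate_abundances()].
#' @param config A [sim_config()].
#' @param out_dir Directory for FASTQ files (created if needed).
#' @return A list: `files` (sample, fastq path), `truth` (read_id, sample,
#'   gene_id), `sample_sheet` (sample, condition, replicate, barcode).
#' @export
simulate_reads <- function(library, abundances, config,
                           out_dir = tempfile("simreads")) {
  stopifnot(inherits(config, "sim_config"))
  library <- as_tibble(library)
  if (!"adaptored_seq" %in% names(library)) {
    abort("library must carry adaptored_seq (run design_library first)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- distinct(abundances, .data$sample, .data$condition,
                    .data$replicate, .data$barcode)
  set.seed(config$seed + 1L)
  truth <- list()
  files <- list()
  for (i in seq_len(nrow(sheet))) {
    smp <- sheet$sample[i]
    ab <- filter(abundances, .data$sample == smp)
    ab <- ab[match(library$gene_id, ab$gene_id), ]
    idx <- sample.int(nrow(library), config$n_reads, replace = TRUE,
                      prob = ab$prob)
    seqs <- paste0(sheet$barcode[i], library$adaptored_seq[idx])
    flip <- runif(config$n_reads) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    seqs <- .corrupt_seq(seqs, config$sub_rate, config$ins_rate,
                         config$del_rate)
    ids <- sprintf("%s_read%06d", smp, seq_len(config$n_reads))
    fq <- file.path(out_dir, paste0(smp, ".fastq"))
    dna <- Biostrings::DNAStringSet(setNames(seqs, ids))
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(dna, fq, format = "fastq", qualities = qual)
    truth[[i]] <- tibble(read_id = ids, sample = smp,
                         gene_id = library$gene_id[idx])
    files[[i]] <- tibble(sample = smp, fastq = fq)
  }
  list(files = bind_rows(files), truth = bind_rows(truth),
       sample_sheet = select(sheet, all_of(c("sample", "condition",
                                             "replicate", "barcode"))))
}

#' Simulate a screen directly at the count level
#'
#' Bypasses read simulation: per-sample counts are independent multinomial
#' draws of `n_reads` reads from the simulated member probabilities. Used
#' for statistical calibration and recovery experiments where sequencing
#' error is not the object of study.
#'
#' @param library Design tibble (or anything with `gene_id`).
#' @param config A [sim_config()].
#' @return A long count tibble (`sample`, `condition`, `replicate`,
#'   `gene_id`, `count`) as produced by the quantification step.
#' @export
simulate_screen_counts <- function(library, config) {
  ab <- simulate_abundances(library, config)
  set.seed(config$seed + 2L)
  ab |>
    group_by(.data$sample, .data$condition, .data$replicate) |>
    mutate(count = as.vector(rmultinom(1L, config$n_reads, .data$prob))) |>
    ungroup() |>
    select(all_of(c("sample", "condition", "replicate", "gene_id", "count")))
}
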