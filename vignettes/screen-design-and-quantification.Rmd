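---
title: "Designing and quantifying pooled CRISPR frameshift-disruption sort-seq screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying pooled CRISPR frameshift-disruption sort-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprsort)
library(dplyr)
```

## The problem

Pooled disruption screens of large gene families — here the yeast
transportome, a set of several hundred transporter genes of which only the
non-essential members are targetable — need two computational layers:

1. **Library design.** For every target gene, pick one SpCas9 guide and
   build a homology-directed-repair (HDR) donor that knocks the gene out in
   a way that is both efficient and sequencing-verifiable. The construct
   used here is a single synthesis fragment carrying the guide, the sgRNA
   scaffold, a terminator, and the repair donor, so that the identity of
   the disrupted gene can later be read out by amplicon sequencing of the
   plasmid itself.
2. **Screen quantification.** After the mutant pool is phenotyped and
   FACS-sorted into high- and low-signal sub-pools (sort-seq with a
   biosensor), amplicon reads from each pool are demultiplexed, assigned to
   library members, counted, and compared between sorted and control pools
   to rank candidate genes.

`crisprsort` implements both layers plus a synthetic-data generator, so the
whole pipeline runs and is testable end to end without any external data.

## The disruption construct

The donor design deliberately avoids full ORF deletion. The package supports
both layouts:

* **Deletion donor (150 bp)** — 75 bp immediately upstream plus 75 bp
  immediately downstream of the ORF, so repair removes the ORF completely.
  Simple, but in the screen's context this layout transforms poorly and
  edits inefficiently, so it is secondary here.
* **Frameshift donor (165 bp)** — homologous to a window inside the ORF.
  The 23 bp protospacer+PAM span is replaced by a 22 bp sequence: a net
  **1 bp deletion** that shifts the reading frame, written so that a
  **premature termination codon (PTC)** appears at or just after the edit.
  Because the PAM is destroyed and the seed region altered, the edited
  locus cannot be re-cut.

The replacement is constructed deterministically, in guide orientation:
drop the base immediately 5' of the PAM (protospacer position 20), rewrite
the PAM's GG to CC, then — only if needed — rewrite up to four seed bases
(positions 15–19), fewest changes first in a fixed position/base order,
until (a) the edited CDS carries a stop codon within the replacement or
ten codons downstream, and (b) the original protospacer no longer matches
anywhere in the edited sequence within two mismatches next to an intact
NGG. Because any three consecutive positions contain a codon start, a full
in-frame codon always lies inside the rewritable window, so a stop can
always be installed; the search nevertheless validates every candidate by
actually translating the edited CDS, which also makes the construction
correct for guides on the antisense strand of the CDS.

Designs whose first stop would fall at or beyond 50% of the original
protein are rejected and the next-ranked guide is tried: a truncation that
late cannot be assumed to disrupt function, and because guides are
preferred in the first quarter of the CDS a compliant PTC is expected
early. Every emitted donor is re-validated by `simulate_hdr_edit()`, which
splices the replacement between the two homology arms (71 bp left, 72 bp
right — the 143 bp of arms cannot be split evenly, and the fixed convention
keeps output byte-reproducible) and checks the 1 bp frameshift, the PTC
position and the re-cut impossibility independently.

## Guide selection

All NGG-adjacent 20-mers on both strands of the CDS are enumerated. Two
**hard filters** are never relaxed: GC fraction ≤ 0.50 and maximum
homopolymer run ≤ 3 (the "repeat" constraint is read as homopolymer runs;
di-/tri-nucleotide motifs are a plausible alternative reading, but runs are
the dominant synthesis and Cas9-activity concern at this length). Position
in the first quarter of the CDS is a **preference**, not a filter: if no
passing guide cuts there, the constraint relaxes to the first half, then
the whole CDS, and the tier used is recorded per gene so the relaxation is
auditable.

Off-target specificity is scored as the minimum Hamming distance from the
candidate's 20-mer to every other PAM-adjacent 20-mer in the supplied
genome (exhaustive scan; the candidate's own genomic site is excluded by
coordinate). Among passing candidates the ranking is: fallback tier, then
maximal off-target distance, then smallest cut site, then lexicographically
smallest protospacer — a total order, so design output is a pure function
of its inputs. Without a genome the off-target criterion is skipped and
flagged `NA` rather than silently scored zero.

## The synthesis fragment

Core fragment = guide (20) + scaffold (79) + terminator (36) + donor (165)
= **300 bp**, flanked by synthesis adaptors totalling **43 bp**. The
default scaffold is the canonical 76 nt SpCas9 tracr scaffold plus a TTT
linker; the default terminator is a generic 36 nt T-rich stand-in for the
yeast SUP4 terminator, and the adaptors are likewise generic. All parts are
plain arguments (`default_parts()`), and real constructs should substitute
their exact sequences; only the lengths enter the design arithmetic.

```{r design}
orfs <- simulate_orfs(6, cds_length = 900, seed = 42)
lib <- design_library(orfs)
lib |> select(gene_id, protospacer, gc, max_run, position_fraction,
              fallback_tier, ptc_codon_index)
design_qc(lib)[c("n_targets", "n_designed")]
```

## What the generator emulates — and what it does not

`sim_config()` fixes the simulated study conditions:

* **Abundance skew**: member probabilities are one log-normal draw
  (default `sdlog = 1`, i.e. roughly a 50-fold central working range).
  Real post-growth yeast pools were considerably more skewed (read counts
  spanning nearly four orders of magnitude); that regime can be emulated
  with a larger `abundance_sdlog`, at the price of frequent dropouts.
  Replicates of a condition share the same true composition; replicate
  noise enters through independent multinomial read draws.
* **Sorting**: each sorted condition multiplies the control composition by
  per-gene fold changes (`spikes`) and renormalises — the idealised view of
  a FACS gate that enriches carriers of particular disruptions.
* **Sequencing error**: i.i.d. per-base substitution/insertion/deletion at
  defaults 5/3/3%, approximating long-read error on an amplicon of a few
  hundred bases. No homopolymer-length bias, no truncation, no chimeras,
  no quality-score realism: reads are full-length, orientation-randomised,
  with constant placeholder qualities.

Passing tests on these simulations therefore demonstrates the *logic* of
assignment and ranking under realistic error loads, not performance on real
nanopore data, whose errors are structured (homopolymer compression in
particular) and correlated.

## Quantification

Reads are demultiplexed by edit distance between each barcode and a short
window at either read end (so barcode indels are tolerated), oriented
forward and trimmed. Assignment is **mapping-free**: each read is compared
by Levenshtein distance to every member's full amplicon sequence and
assigned to the unique minimiser within 15% of the member length —
roughly three times the default per-base error rate, keeping random
cross-member hits rare while absorbing the expected error load. Ties are
ambiguous and counted in neither member (conservative and reproducible, at
the cost of discarding a small number of reads); reads beyond the
threshold are unassigned. Per-sample `assigned + ambiguous + unassigned`
always equals reads processed.

Representation QC (`library_uniformity()`) reports dropouts (members with
zero reads — in the real library three such members were detectable only
by PCR), the count fold-range, and the Gini coefficient of the Lorenz
curve of counts.

## The screen statistic

Frequencies are counts over per-sample totals, with a **pseudocount of
0.5** in every cell (dropout members are a fact of these libraries and the
ratio statistic must stay finite; 0.5 is the standard continuity
correction). The **enrichment score** of a gene is its mean sorted-pool
frequency divided by its mean control frequency; per-replicate frequencies
are kept alongside and averaged (computing scores per replicate and
averaging afterwards is an equally defensible reading; both views are
recoverable from the output's list columns). Significance across
replicates uses a **two-tailed pooled-variance Student's t-test**: at
three replicates per pool the Welch–Satterthwaite approximation is
measurably conservative (simulated null type-I error ≈ 0.035 at nominal
0.05), while the pooled test stays calibrated (≈ 0.048), and the pools
being compared are technically comparable samples with similar dispersion.
Benjamini–Hochberg q-values are attached across genes within each
contrast.

Ranking is directional: descending log2 score for a `max` contrast,
ascending for `min`, ties broken by gene id. The selection size is a
parameter (`rank_candidates(top_n = ...)`) rather than a hidden threshold.
A count matrix export plus this ranking is deliberately the native
statistic; differential-abundance modelling of counts (e.g. with DESeq2)
is treated as an external secondary analysis, out of proportion to
re-implement here.

```{r screen}
genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:100))
cfg <- sim_config(n_reads = 2e4, spikes = list(max = c(g007 = 4, g042 = 4)),
                  conditions = c("control", "max"), n_replicates = 3,
                  seed = 7)
res <- screen_enrichment(simulate_screen_counts(genes, cfg), "max")
head(tidy(res))
glance(res)
```

## Numerical and scale choices

* Coordinates are 0-based half-open internally and 1-based inclusive at
  every I/O boundary.
* Ambiguity codes in input genomes disqualify any overlapping guide or
  donor window; there is no defensible design over unknown bases.
* Design, simulation and quantification are deterministic given their
  inputs and seeds; every randomised routine takes a mandatory seed.
* Test and example problem sizes (50–411 genes, CDSs of 300–900 nt,
  10²–10⁵ reads per sample) were chosen as the smallest scales at which
  each property is statistically meaningful — e.g. spike recovery and
  type-I calibration use 10⁵ reads over 200–1000 genes, matching the order
  of magnitude of the real screen's per-sample read counts.

## Known limitations

* Off-target scoring is exact Hamming distance to other PAM-adjacent
  sites — no bulges, no activity-weighted mismatch models, no
  machine-learned efficiency scores.
* The error model is i.i.d.; real long-read error is structured.
* Amplicon assignment assumes the member references are the full
  adaptored fragments; partial reads would need a banded/local variant.
* The GFF3 annotation reader is a convenience layer; the canonical input
  is the tabular annotation (gene lists for screens of this kind are
  curated tables, not alignment artifacts).
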