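Package: crisprsort
Title: Design and Quantification of Pooled CRISPR Frameshift-Disruption
    Sort-Seq Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based design of sgRNA plus frameshift homology-directed-repair
    donor constructs for pooled gene disruption libraries (guide filtering by GC
    content, homopolymer runs, position within the coding sequence and genome-wide
    off-target mismatch; 165 bp donors replacing the 23 bp protospacer-PAM span
    with a 22 bp sequence that installs a premature termination codon via a 1 bp
    frameshift; 300 bp synthesis fragments), together with a synthetic sort-seq
    data generator, error-tolerant amplicon read quantification into per-gene
    count tables, and enrichment-score statistics (frequency ratios, t-tests,
    Benjamini-Hochberg correction, candidate ranking) for sorted versus control
    pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    seqinr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
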