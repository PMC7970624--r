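#' Library design rules
#'
#' Bundles the numeric constraints of the disruption-library design: guide
#' hard filters (GC content, homopolymer run), the positional preference for
#' the first quarter of the CDS, and the fixed construct arithmetic — a
#' 165 bp frameshift donor in which the 23 bp protospacer+PAM span is
#' replaced by a 22 bp sequence (net 1 bp deletion), a 150 bp full-ORF
#' deletion donor, and a 300 bp synthesis core flanked by 43 bp of adaptors.
#'
#' @param pam PAM motif (only `"NGG"` is supported).
#' @param guide_len Protospacer length in nt.
#' @param gc_max Maximum allowed GC fraction of the protospacer (hard filter).
#' @param max_run Maximum allowed homopolymer run in the protospacer (hard
#'   filter).
#' @param position_fraction_max Preferred upper bound on cut-site position as
#'   a fraction of CDS length; relaxed in tiers (1/4, 1/2, whole CDS), never
#'   silently.
#' @param donor_len Frameshift donor length (nt).
#' @param replaced_span Length of the replaced protospacer+PAM span (nt).
#' @param replacement_len Length of the replacement written by the donor (nt);
#'   must be `replaced_span - 1` (the 1 bp frameshift).
#' @param left_arm_len,right_arm_len Homology arm lengths; must sum with
#'   `replacement_len` to `donor_len`.
#' @param deletion_donor_len Full-ORF deletion donor length (nt), split into
#'   two equal flanks.
#' @param fragment_len Required length of the assembled synthesis core.
#' @param adaptor_len_total Combined length of the 5' and 3' synthesis
#'   adaptors.
#' @param ptc_max_fraction Designs whose first stop codon in the edited frame
#'   falls at or beyond this fraction of the original protein are rejected.
#' @return A list of class `design_rules`.
#' @export
design_rules <- function(pam = "NGG", guide_len = 20L, gc_max = 0.50,
                         max_run = 3L, position_fraction_max = 0.25,
                         donor_len = 165L, replaced_span = 23L,
                         replacement_len = 22L,
                         left_arm_len = 71L, right_arm_len = 72L,
                         deletion_donor_len = 150L, fragment_len = 300L,
                         adaptor_len_total = 43L, ptc_max_fraction = 0.5) {
  if (!identical(toupper(pam), "NGG")) {
    abort("only the SpCas9 NGG PAM is supported")
  }
  if (replaced_span - replacement_len != 1L) {
    abort("replaced_span - replacement_len must be 1 (the frameshift)")
  }
  if (left_arm_len + replacement_len + right_arm_len != donor_len) {
    abort(sprintf("arm/replacement arithmetic broken: %d + %d + %d != %d",
                  left_arm_len, replacement_len, right_arm_len, donor_len))
  }
  if (replaced_span != guide_len + 3L) {
    abort("replaced_span must equal guide_len + PAM length (3)")
  }
  structure(
    list(pam = "NGG", guide_len = as.integer(guide_len), gc_max = gc_max,
         max_run = as.integer(max_run),
         position_fraction_max = position_fraction_max,
         donor_len = as.integer(donor_len),
         replaced_span = as.integer(replaced_span),
         replacement_len = as.integer(replacement_len),
         left_arm_len = as.integer(left_arm_len),
         right_arm_len = as.integer(right_arm_len),
         deletion_donor_len = as.integer(deletion_donor_len),
         fragment_len = as.integer(fragment_len),
         adaptor_len_total = as.integer(adaptor_len_total),
         ptc_max_fraction = ptc_max_fraction),
    class = "design_rules"
  )
}

#' Default constant parts for fragment assembly
#'
#' The scaffold is the canonical 76 nt SpCas9 tracr scaffold with a TTT
#' linker (79 nt total). The terminator is a generic 36 nt T-rich stand-in
#' for the yeast SUP4 terminator, and the adaptors are generic synthesis
#' adaptors (21 + 22 = 43 nt); replace any of them with your construct's
#' exact sequences. With a 20 nt guide and 165 nt donor the default parts
#' give a 300 nt core.
#'
#' @return A named list with `scaffold`, `terminator`, `adaptor5`, `adaptor3`.
#' @export
default_parts <- function() {
  list(
    scaffold = paste0(
      "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGG",
      "CACCGAGTCGGTGC", "TTT"
    ),
    terminator = "TTTTTTTGTTTTTTATGTCTTGTTTCTTTTTTTGTT",
    adaptor5 = "AGGCACTTGCTCGTACGACGC",
    adaptor3 = "GCGTAAGGATCTGAGCTACACG"
  )
}
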