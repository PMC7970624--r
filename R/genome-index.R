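.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.encode_kmers <- function(kmers, k) {
  m <- matrix(.BASE_CODE[unlist(strsplit(kmers, "", fixed = TRUE))],
              ncol = k, byrow = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Index every PAM-adjacent protospacer site in a genome
#'
#' Exhaustively records, on both strands of every contig, each 20-mer that
#' lies immediately 5' of an NGG PAM. Positions are 0-based starts of the
#' protospacer on the forward (plus) strand coordinates; minus-strand sites
#' store the forward-strand start of the 20-mer whose reverse complement is
#' the protospacer. Windows containing ambiguity codes are skipped. The
#' returned object is the substrate for the off-target minimum-mismatch
#' criterion of guide selection.
#'
#' @param contigs FASTA path, named character vector or DNAStringSet.
#' @param guide_len Protospacer length (default 20).
#' @return An object of class `genome_index`: a list with `sites` (tibble:
#'   `contig`, `pos` 0-based, `strand`, `protospacer`) and contig lengths.
#' @export
genome_index <- function(contigs, guide_len = 20L) {
  contigs <- .read_contigs(contigs)
  one <- function(nm) {
    s <- contigs[[nm]]
    n <- nchar(s)
    if (n < guide_len + 3L) {
      return(tibble(contig = character(), pos = integer(),
                    strand = character(), protospacer = character()))
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    # plus strand: protospacer [p, p+19], PAM [p+20, p+22] with GG at p+21..p+22
    gg <- which(ch[-n] == "G" & ch[-1] == "G")          # 1-based start of GG
    p_plus <- gg - guide_len - 1L
    p_plus <- p_plus[p_plus >= 1L]
    # minus strand: forward shows CCN at [c, c+2], 20-mer at [c+3, c+22]
    cc <- which(ch[-n] == "C" & ch[-1] == "C")
    c_minus <- cc[cc + guide_len + 2L <= n]
    plus <- tibble(
      contig = nm, pos = p_plus - 1L, strand = "+",
      protospacer = substring(s, p_plus, p_plus + guide_len - 1L)
    )
    minus <- tibble(
      contig = nm, pos = c_minus + 2L, strand = "-",
      protospacer = revcomp(substring(s, c_minus + 3L, c_minus + guide_len + 2L))
    )
    out <- bind_rows(plus, minus)
    out[!grepl("[^ACGT]", out$protospacer), , drop = FALSE]
  }
  sites <- bind_rows(lapply(names(contigs), one))
  enc <- if (nrow(sites) > 0L) .encode_kmers(sites$protospacer, guide_len) else
    matrix(integer(), ncol = guide_len)
  structure(
    list(sites = sites, enc = enc, guide_len = guide_len,
         contig_len = setNames(nchar(contigs), names(contigs))),
    class = "genome_index"
  )
}

#' @method print genome_index
#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index: %d PAM-adjacent %d-mer sites on %d contig(s)>\n",
              nrow(x$sites), x$guide_len, length(x$contig_len)))
  invisible(x)
}

# Minimum Hamming distance from each query protospacer to every indexed site,
# excluding the query's own site (identified by contig:pos:strand key when
# given, else by discounting one exact-match site).
.offtarget_min_mismatch <- function(index, protospacers, self_keys = NULL) {
  stopifnot(inherits(index, "genome_index"))
  S <- nrow(index$sites)
  if (S == 0L) return(rep(NA_integer_, length(protospacers)))
  k <- index$guide_len
  site_keys <- paste(index$sites$contig, index$sites$pos, index$sites$strand,
                     sep = ":")
  q_enc <- .encode_kmers(protospacers, k)
  vapply(seq_along(protospacers), function(i) {
    mm <- integer(S)
    for (j in seq_len(k)) mm <- mm + (index$enc[, j] != q_enc[i, j])
    if (!is.null(self_keys) && !is.na(self_keys[i])) {
      mm[site_keys == self_keys[i]] <- NA_integer_
    } else {
      z <- which(mm == 0L)
      if (length(z) > 0L) mm[z[1]] <- NA_integer_
    }
    if (all(is.na(mm))) NA_integer_ else as.integer(min(mm, na.rm = TRUE))
  }, integer(1))
}
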