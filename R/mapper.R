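# Minimal seed-and-extend read mapper over the mini-genome. Ungapped,
# end-to-end, mismatch-only: the desk-scale stand-in for a production
# short-read aligner, and the source of the unmapped-read pool the fusion
# scanner consumes.

#' Build a k-mer index of a genome
#'
#' @param genome A `genome_fixture` or a plain sequence string.
#' @param k K-mer size (2-31; default 15).
#' @return A `kmer_index` object.
#' @export
build_index <- function(genome, k = 15L) {
  seq <- genome_sequence(genome)
  structure(list(ptr = cpp_build_index(seq, as.integer(k)),
                 k = as.integer(k),
                 genome = seq,
                 chrom = if (inherits(genome, "genome_fixture")) genome$chrom
                         else "ref",
                 genome_length = nchar(seq)),
            class = "kmer_index")
}

#' Look up a k-mer in the index
#'
#' @param index A `kmer_index`.
#' @param kmer A string of length `index$k`.
#' @return Data.frame of `pos` (1-based) and `strand` (`+` where the k-mer
#'   matches the forward genome, `-` where its reverse complement does).
#' @export
index_lookup <- function(index, kmer) {
  hits <- cpp_index_lookup(index$ptr, kmer)
  data.frame(pos = hits$pos, strand = hits$strand,
             stringsAsFactors = FALSE)
}

#' Map a single read
#'
#' Best ungapped end-to-end placement by mismatch count. Unmapped when no
#' seed hits or the best placement exceeds `max_mismatch_frac` of the read
#' length. Ties at the best count report the lowest coordinate with MAPQ 0;
#' a unique best with no runner-up gets MAPQ 60, otherwise MAPQ scales with
#' the gap to the second-best placement.
#'
#' @param index A `kmer_index`.
#' @param read Read sequence string.
#' @param max_mismatch_frac Mismatch budget as a fraction of read length.
#' @return One-row data.frame: pos, strand, mismatches, mapq, mapped.
#' @export
map_read <- function(index, read, max_mismatch_frac = 0.05) {
  cpp_map_reads(index$ptr, read, max_mismatch_frac)
}

#' Map a sample's reads, separating the unmapped pool
#'
#' Every input read appears exactly once in the output: either as a SAM
#' record (mapped) or in the unmapped pool. Input order is preserved. Mates
#' are handled independently (ungapped single-end placement per mate); an
#' orphan mate triggers a warning and is processed single-end.
#'
#' @param index A `kmer_index`.
#' @param reads Read data.frame (`qname`, `mate`, `seq`, `qual`).
#' @param max_mismatch_frac Mismatch budget as a fraction of read length.
#' @return List with `sam` (mapped records, SAM columns + `nm`) and
#'   `unmapped` (read data.frame).
#' @export
map_sample <- function(index, reads, max_mismatch_frac = 0.05) {
  if (nrow(reads) == 0L) return(list(sam = empty_sam(), unmapped = reads))
  paired <- !is.na(reads$mate)
  if (any(paired)) {
    tab <- table(reads$qname[paired])
    if (any(tab != 2L)) {
      warning(sum(tab != 2L), " orphan mate(s); processed single-end")
    }
  }
  res <- cpp_map_reads(index$ptr, reads$seq, max_mismatch_frac)
  mapped <- res$mapped
  sam <- NULL
  if (any(mapped)) {
    m <- which(mapped)
    minus <- res$strand[m] == "-"
    seq_out <- reads$seq[m]
    qual_out <- reads$qual[m]
    if (any(minus)) {
      seq_out[minus] <- revcomp(seq_out[minus])
      qual_out[minus] <- vapply(qual_out[minus], function(q) {
        intToUtf8(rev(utf8ToInt(q)))
      }, character(1), USE.NAMES = FALSE)
    }
    flag <- ifelse(is.na(reads$mate[m]), 0L,
                   1L + ifelse(reads$mate[m] == 1L, 64L, 128L))
    flag <- flag + ifelse(minus, 16L, 0L)
    sam <- data.frame(
      qname = reads$qname[m], flag = flag, rname = index$chrom,
      pos = res$pos[m], mapq = res$mapq[m],
      cigar = paste0(nchar(seq_out), "M"),
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = seq_out, qual = qual_out, nm = res$mismatches[m],
      row.names = NULL, stringsAsFactors = FALSE)
    sam$unmapped <- FALSE
  } else {
    sam <- empty_sam()
  }
  list(sam = sam, unmapped = reads[!mapped, , drop = FALSE])
}
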