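# Readers/writers for every on-disk format the pipeline touches. All other
# modules do file I/O through this layer. Coordinates are 1-based inclusive
# everywhere except BED files on disk (0-based half-open); the BED reader and
# writer convert, so in-memory tables are always 1-based.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (full header line after `>`,
#'   preserved verbatim) and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- names(x)
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  data.frame(id = ids, sequence = as.character(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records Data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (any(!nzchar(records$id))) stop("FASTA record ids must be non-empty")
  if (any(nchar(records$sequence) < 1L)) stop("FASTA sequences must be non-empty")
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Convert a quality string to phred scores and back
#'
#' Sanger (+33) encoding only; other encodings are rejected.
#'
#' @param qual A single quality string.
#' @return Integer vector of phred scores.
#' @export
qual_to_phred <- function(qual) {
  v <- utf8ToInt(qual) - 33L
  if (any(v < 0L | v > 60L)) {
    stop("quality string is not Sanger +33 encoded (phred outside [0, 60])")
  }
  v
}

#' @rdname qual_to_phred
#' @param phred Integer vector of phred scores (0-60).
#' @export
phred_to_qual <- function(phred) {
  if (any(phred < 0L | phred > 60L)) stop("phred scores must be in [0, 60]")
  intToUtf8(phred + 33L)
}

#' Read / write FASTQ
#'
#' Reads are returned as a data.frame with one row per read: `qname` (id with
#' any `/1` `/2` mate suffix stripped), `mate` (1, 2 or NA for single-end),
#' `seq` and `qual` (Sanger +33 string).
#'
#' @param path File path.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  lapply(q, qual_to_phred)  # validates encoding
  ids <- names(x)
  has_mate <- grepl("/[12]$", ids)
  mate <- rep(NA_integer_, length(ids))
  mate[has_mate] <- as.integer(sub(".*/([12])$", "\\1", ids[has_mate]))
  data.frame(
    qname = sub("/[12]$", "", ids),
    mate = mate,
    seq = as.character(x),
    qual = q,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads Data.frame as returned by [read_fastq()].
#' @export
write_fastq <- function(reads, path) {
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("seq/qual length mismatch")
  }
  ids <- ifelse(is.na(reads$mate), reads$qname,
                paste0(reads$qname, "/", reads$mate))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Read / write SAM alignments
#'
#' A deliberately narrow text-SAM subset: the 11 mandatory columns plus the
#' optional NM (mismatch count) tag the internal mapper emits. Header lines
#' are skipped on read; headerless files are accepted.
#'
#' @param path File path.
#' @return Data.frame with the 11 mandatory SAM columns, an `nm` column
#'   (NA when absent) and a derived logical `unmapped` (flag bit 0x4).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(empty_sam())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    stop("malformed SAM record at data line ", which(nf < 11L)[1L])
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  pos_chr <- get(4)
  if (any(!grepl("^[0-9]+$", pos_chr))) {
    stop("non-numeric POS at data line ", which(!grepl("^[0-9]+$", pos_chr))[1L])
  }
  nm <- vapply(parts, function(p) {
    tag <- grep("^NM:i:", p[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
  }, integer(1))
  out <- data.frame(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(pos_chr), mapq = as.integer(get(5)), cigar = get(6),
    rnext = get(7), pnext = as.integer(get(8)), tlen = as.integer(get(9)),
    seq = get(10), qual = get(11), nm = nm,
    row.names = NULL, stringsAsFactors = FALSE)
  out$unmapped <- bitwAnd(out$flag, 4L) > 0L
  mapped_bad <- !out$unmapped & out$pos < 1L
  if (any(mapped_bad)) stop("mapped SAM record with POS < 1")
  out
}

empty_sam <- function() {
  out <- data.frame(qname = character(), flag = integer(), rname = character(),
                    pos = integer(), mapq = integer(), cigar = character(),
                    rnext = character(), pnext = integer(), tlen = integer(),
                    seq = character(), qual = character(), nm = integer(),
                    stringsAsFactors = FALSE)
  out$unmapped <- logical()
  out
}

#' @rdname read_sam
#' @param records Data.frame of SAM records.
#' @param header Optional character vector of header lines (written verbatim).
#' @export
write_sam <- function(records, path, header = NULL) {
  body <- character(0)
  if (nrow(records)) {
    tag <- ifelse(is.na(records$nm), "", paste0("\tNM:i:", records$nm))
    body <- paste0(records$qname, "\t", records$flag, "\t", records$rname, "\t",
                   records$pos, "\t", records$mapq, "\t", records$cigar, "\t",
                   records$rnext, "\t", records$pnext, "\t", records$tlen, "\t",
                   records$seq, "\t", records$qual, tag)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write the package's VCF subset
#'
#' VCFv4.2 with columns CHROM..INFO only. Alleles must be single nucleotides
#' (the calling pipeline excludes indels) and REF must differ from ALT.
#'
#' @param path File path.
#' @return Data.frame with columns chrom, pos, id, ref, alt, qual, filter, info.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_vcf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 8L)) stop("malformed VCF data line")
  get <- function(i) vapply(parts, `[[`, character(1), i)
  pos_chr <- get(2)
  if (any(!grepl("^[0-9]+$", pos_chr))) stop("non-numeric POS in VCF")
  out <- data.frame(
    chrom = get(1), pos = as.integer(pos_chr), id = get(3),
    ref = get(4), alt = get(5),
    qual = suppressWarnings(as.numeric(get(6))),
    filter = get(7), info = get(8),
    row.names = NULL, stringsAsFactors = FALSE)
  validate_vcf_alleles(out)
  out
}

empty_vcf <- function() {
  data.frame(chrom = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), qual = numeric(),
             filter = character(), info = character(),
             stringsAsFactors = FALSE)
}

validate_vcf_alleles <- function(v) {
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L)) {
    stop("only single-nucleotide alleles are supported")
  }
  if (any(v$ref == v$alt)) stop("REF equals ALT in VCF record")
  invisible(v)
}

#' @rdname read_vcf
#' @param records VCF data.frame (as from [read_vcf()] or [as_vcf_records()]).
#' @export
write_vcf <- function(records, path) {
  validate_vcf_alleles(records)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt-supporting read count\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=PV4,Number=4,Type=Float,Description=\"P-values: strand, baseQ, mapQ, end-distance bias\">",
    "##INFO=<ID=GT,Number=1,Type=String,Description=\"Called genotype class\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  qual <- ifelse(is.na(records$qual), ".", format(records$qual, trim = TRUE,
                                                  scientific = FALSE))
  body <- if (nrow(records)) {
    paste(records$chrom, records$pos, records$id, records$ref, records$alt,
          qual, records$filter, records$info, sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Convert variant calls to VCF records
#'
#' Packs the call annotations (DP, alt count, RMS MQ, PV4 quartet, genotype,
#' and any consequence annotation) into the INFO column.
#'
#' @param calls A calls data.frame as produced by [call_sample()].
#' @export
as_vcf_records <- function(calls) {
  if (nrow(calls) == 0L) return(empty_vcf())
  info <- paste0(
    "DP=", calls$dp, ";AC=", calls$alt_count,
    ";MQ=", formatC(calls$rms_mq, format = "fg", digits = 6),
    ";PV4=", signif(calls$p_strand, 6), ",", signif(calls$p_baseq, 6), ",",
    signif(calls$p_mapq, 6), ",", signif(calls$p_end, 6),
    ";GT=", calls$genotype)
  if (!is.null(calls$csq)) {
    info <- paste0(info, ";CSQ=", calls$csq, ";IMPACT=", calls$impact,
                   ";GENE=", ifelse(is.na(calls$gene), ".", calls$gene))
  }
  filter <- if (is.null(calls$filter)) "PASS" else calls$filter
  data.frame(chrom = calls$chrom, pos = calls$pos, id = ".",
             ref = calls$ref, alt = calls$alt,
             qual = round(calls$qual, 2), filter = filter, info = info,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Parse a VCF INFO string into a named list
#' @param info A single INFO string, e.g. `"DP=30;AC=15"`.
#' @export
parse_info <- function(info) {
  fields <- strsplit(info, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  setNames(lapply(kv, function(x) if (length(x) > 1L) x[[2L]] else TRUE),
           vapply(kv, `[[`, character(1), 1L))
}

#' Write gene models as GFF3 / read them back
#'
#' Gene models are lists with elements `gene_id`, `strand`, `tx_start`,
#' `tx_end`, `exons` (two-column matrix of start, end), and `cds`
#' (`c(start, end)` or NULL for non-coding genes).
#'
#' @param genes List of gene models.
#' @param chrom Chromosome name.
#' @param path Output path.
#' @export
write_gff <- function(genes, chrom, path) {
  rows <- list()
  for (g in genes) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = g$tx_start, end = g$tx_end, strand = g$strand,
      type = "gene", id = g$gene_id, parent = NA_character_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      start = g$exons[, 1L], end = g$exons[, 2L], strand = g$strand,
      type = "exon",
      id = paste0(g$gene_id, ".exon", seq_len(nrow(g$exons))),
      parent = g$gene_id, stringsAsFactors = FALSE)
    if (!is.null(g$cds)) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = g$cds[1L], end = g$cds[2L], strand = g$strand,
        type = "CDS", id = paste0(g$gene_id, ".cds"), parent = g$gene_id,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$phase <- ifelse(tab$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- tab$id
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    ifelse(is.na(tab$parent), list(character(0)), as.list(tab$parent)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(S4Vectors::mcols(gr)$type)
  id <- as.character(S4Vectors::mcols(gr)$ID)
  parent <- vapply(S4Vectors::mcols(gr)$Parent, function(p) {
    if (length(p)) p[[1L]] else NA_character_
  }, character(1))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-") & type == "gene")) {
    stop("unknown strand in gene feature")
  }
  genes <- list()
  for (i in which(type == "gene")) {
    gid <- id[i]
    ex <- which(type == "exon" & parent == gid)
    ex <- ex[order(st[ex])]
    exons <- cbind(start = st[ex], end = en[ex])
    ci <- which(type == "CDS" & parent == gid)
    genes[[gid]] <- list(
      gene_id = gid, strand = strand[i],
      tx_start = st[i], tx_end = en[i], exons = exons,
      cds = if (length(ci)) c(st[ci[1L]], en[ci[1L]]) else NULL)
  }
  genes
}

#' Read / write BED intervals
#'
#' On disk BED is 0-based half-open; in memory intervals are 1-based
#' inclusive, so `read_bed(write_bed(x)) == x`.
#'
#' @param intervals Data.frame with columns chrom, start, end and optionally
#'   name (1-based inclusive).
#' @param path File path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(intervals$start, intervals$end))
  if (!is.null(intervals$name)) S4Vectors::mcols(gr)$name <- intervals$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (length(readLines(path)) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = if (is.null(nm)) NA_character_ else as.character(nm),
             row.names = NULL, stringsAsFactors = FALSE)
}

# BED coordinate converters (exact inverse bijections, property-tested)
to_bed_coords <- function(start1, end1) list(start = start1 - 1L, end = end1)
from_bed_coords <- function(start0, end0) list(start = start0 + 1L, end = end0)

#' Read / write GMT pathway gene-set files
#'
#' @param path File path (`pathway<TAB>description<TAB>gene1<TAB>...`).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param pathways Named list of character vectors.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a variant truth table
#'
#' @param truth A truth set from [implant_variants()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth$variants, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, quote = "", comment.char = "")
}
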