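# Consequence classification of SNVs against gene models, in the style of a
# variant effect predictor reduced to a closed, ordered vocabulary. Each
# variant receives exactly one most-severe term; severity order and the
# term -> impact map are fixed tables.

#' The closed consequence vocabulary, most severe first
#' @export
consequence_terms <- function() {
  c("splice_donor_variant", "splice_acceptor_variant", "stop_gained",
    "missense_variant", "splice_region_variant", "synonymous_variant",
    "5_prime_UTR_variant", "3_prime_UTR_variant",
    "non_coding_transcript_exon_variant", "intron_variant",
    "upstream_gene_variant", "downstream_gene_variant",
    "TF_binding_site_variant", "regulatory_region_variant",
    "intergenic_variant")
}

#' Impact class of a consequence term
#' @param term Character vector of consequence terms.
#' @export
consequence_impact <- function(term) {
  high <- c("splice_donor_variant", "splice_acceptor_variant", "stop_gained")
  low <- c("splice_region_variant", "synonymous_variant")
  ifelse(term %in% high, "HIGH",
         ifelse(term == "missense_variant", "MODERATE",
                ifelse(term %in% low, "LOW", "MODIFIER")))
}

# spliced transcript positions in 5'->3' order
spliced_positions <- function(gene) {
  p <- unlist(lapply(seq_len(nrow(gene$exons)), function(e) {
    gene$exons[e, 1L]:gene$exons[e, 2L]
  }))
  if (gene$strand == "-") rev(p) else p
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# term for a position relative to one gene, or NA when outside the gene's
# 5 kb neighbourhood entirely
gene_term <- function(gene, pos, gseq, alt, flank = 5000L) {
  ex <- gene$exons
  n_ex <- nrow(ex)
  if (pos < gene$tx_start || pos > gene$tx_end) {
    if (pos < gene$tx_start && pos >= gene$tx_start - flank) {
      return(if (gene$strand == "+") "upstream_gene_variant"
             else "downstream_gene_variant")
    }
    if (pos > gene$tx_end && pos <= gene$tx_end + flank) {
      return(if (gene$strand == "+") "downstream_gene_variant"
             else "upstream_gene_variant")
    }
    return(NA_character_)
  }
  exon_i <- which(pos >= ex[, 1L] & pos <= ex[, 2L])
  if (length(exon_i) == 0L) {
    # intronic: distances into the intron from the flanking exons
    prev <- max(which(ex[, 2L] < pos))
    d5 <- pos - ex[prev, 2L]          # bases past the left exon end
    d3 <- ex[prev + 1L, 1L] - pos     # bases before the right exon start
    if (gene$strand == "+") {
      if (d5 <= 2L) return("splice_donor_variant")
      if (d3 <= 2L) return("splice_acceptor_variant")
    } else {
      if (d3 <= 2L) return("splice_donor_variant")
      if (d5 <= 2L) return("splice_acceptor_variant")
    }
    if ((d5 >= 3L && d5 <= 8L) || (d3 >= 3L && d3 <= 8L)) {
      return("splice_region_variant")
    }
    return("intron_variant")
  }
  exon_i <- exon_i[1L]
  # exonic: splice-region candidate when within 3 bases of an internal edge
  region <- FALSE
  if (exon_i > 1L && pos - ex[exon_i, 1L] < 3L) region <- TRUE
  if (exon_i < n_ex && ex[exon_i, 2L] - pos < 3L) region <- TRUE
  base_term <- exonic_term(gene, pos, gseq, alt)
  terms <- consequence_terms()
  cand <- c(base_term, if (region) "splice_region_variant")
  cand[which.min(match(cand, terms))]
}

exonic_term <- function(gene, pos, gseq, alt) {
  if (is.null(gene$cds)) return("non_coding_transcript_exon_variant")
  if (pos < gene$cds[1L] || pos > gene$cds[2L]) {
    before <- pos < gene$cds[1L]
    five <- if (gene$strand == "+") before else !before
    return(if (five) "5_prime_UTR_variant" else "3_prime_UTR_variant")
  }
  sp <- spliced_positions(gene)
  cds_sp <- sp[sp >= gene$cds[1L] & sp <= gene$cds[2L]]
  idx <- match(pos, cds_sp)
  if (is.na(idx)) {
    # inside the genomic CDS interval but intronic base: handled by caller
    return("intron_variant")
  }
  codon_i <- (idx - 1L) %/% 3L
  slot <- (idx - 1L) %% 3L + 1L
  cpos <- cds_sp[codon_i * 3L + 1:3]
  if (any(is.na(cpos))) return("missense_variant")  # trailing partial codon
  bases <- substring(gseq, cpos, cpos)
  if (gene$strand == "-") bases <- COMPLEMENT[bases]
  ref_codon <- paste(bases, collapse = "")
  alt_bases <- bases
  alt_bases[slot] <- if (gene$strand == "-") COMPLEMENT[[alt]] else alt
  alt_codon <- paste(alt_bases, collapse = "")
  code <- Biostrings::GENETIC_CODE
  ref_aa <- code[[ref_codon]]
  alt_aa <- code[[alt_codon]]
  if (alt_aa == "*" && ref_aa != "*") return("stop_gained")
  if (alt_aa == ref_aa) return("synonymous_variant")
  "missense_variant"  # includes start/stop-loss, folded into the vocabulary
}

in_intervals <- function(pos, intervals) {
  nrow(intervals) > 0L && any(pos >= intervals$start & pos <= intervals$end)
}

#' Classify one variant
#'
#' Deterministic most-severe classification across all gene models and the
#' regulatory/TF interval sets, by the fixed severity order of
#' [consequence_terms()]. Splice donor/acceptor are the first/last two
#' intronic bases; the splice region covers exonic bases 1-3 and intronic
#' bases 3-8 from a junction; coding terms are derived by codon translation
#' on the gene's strand; up/downstream extend 5 kb from the transcript.
#'
#' @param genome A `genome_fixture` (carries gene models and interval sets).
#' @param pos,ref,alt Variant position and alleles; `ref` must equal the
#'   genome base at `pos`.
#' @param flank Up/downstream window (bp).
#' @return List: `term`, `impact`, `gene` (NA when no gene is involved).
#' @export
classify_variant <- function(genome, pos, ref, alt, flank = 5000L) {
  gseq <- genome$sequence
  if (pos < 1L || pos > genome$length) stop("variant outside genome bounds")
  gbase <- substring(gseq, pos, pos)
  if (gbase != ref) {
    stop("variant ref '", ref, "' disagrees with genome base '", gbase,
         "' at ", pos)
  }
  terms <- consequence_terms()
  best <- "intergenic_variant"
  best_gene <- NA_character_
  for (gene in genome$genes) {
    tm <- gene_term(gene, pos, gseq, alt, flank = flank)
    if (!is.na(tm) && match(tm, terms) < match(best, terms)) {
      best <- tm
      best_gene <- gene$gene_id
    }
  }
  if (in_intervals(pos, genome$tf_sites) &&
      match("TF_binding_site_variant", terms) < match(best, terms)) {
    best <- "TF_binding_site_variant"
    best_gene <- NA_character_
  }
  if (in_intervals(pos, genome$regulatory) &&
      match("regulatory_region_variant", terms) < match(best, terms)) {
    best <- "regulatory_region_variant"
    best_gene <- NA_character_
  }
  list(term = best, impact = consequence_impact(best), gene = best_gene)
}

#' Annotate a calls table with consequences
#'
#' Adds `csq`, `impact` and `gene` columns via [classify_variant()].
#'
#' @param calls Calls data.frame.
#' @param genome A `genome_fixture`.
#' @export
annotate_variants <- function(calls, genome) {
  if (nrow(calls) == 0L) {
    calls$csq <- character(0); calls$impact <- character(0)
    calls$gene <- character(0)
    return(calls)
  }
  ann <- lapply(seq_len(nrow(calls)), function(i) {
    classify_variant(genome, calls$pos[i], calls$ref[i], calls$alt[i])
  })
  calls$csq <- vapply(ann, `[[`, character(1), "term")
  calls$impact <- vapply(ann, `[[`, character(1), "impact")
  calls$gene <- vapply(ann, `[[`, character(1), "gene")
  calls
}

#' Consequence summary table
#'
#' Counts and percentages per term, emitted in the fixed vocabulary order.
#' Percentages sum to 100 (up to rounding); an empty input yields an
#' all-zero table.
#'
#' @param terms Character vector of consequence terms (e.g. the `csq`
#'   column of an annotated calls table).
#' @export
consequence_table <- function(terms) {
  lv <- consequence_terms()
  bad <- setdiff(unique(terms), lv)
  if (length(bad)) stop("unknown consequence term: ", paste(bad, collapse = ", "))
  counts <- table(factor(terms, levels = lv))
  n <- length(terms)
  data.frame(term = lv, impact = consequence_impact(lv),
             count = as.integer(counts),
             pct = if (n) as.numeric(counts) / n * 100 else rep(0, length(lv)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep only HIGH-impact annotated calls
#' @param calls Annotated calls data.frame (with an `impact` column).
#' @export
high_impact_filter <- function(calls) {
  calls[calls$impact == "HIGH", , drop = FALSE]
}
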