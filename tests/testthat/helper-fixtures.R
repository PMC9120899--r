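# Shared fixtures and independent oracles, all built in code.

# hand-built genome fixture for consequence tests: one forward-strand gene
# with two exons and controlled codon content, plus distal regulatory and
# TF intervals beyond the 5 kb gene neighbourhood.
manual_gene_fixture <- function() {
  set.seed(4711)
  L <- 8000L
  seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # gene: tx 101-340, exon1 101-160, intron 161-220, exon2 221-340
  # spliced length 180; CDS spliced 31..150 -> genomic 131..310
  seqv[131:133] <- c("C", "G", "A")  # codon 1: CGA (Arg)
  seqv[158:160] <- c("C", "T", "C")  # codon 10: CTC (Leu)
  seq <- paste(seqv, collapse = "")
  gene <- list(gene_id = "geneA", strand = "+", tx_start = 101L,
               tx_end = 340L,
               exons = cbind(start = c(101L, 221L), end = c(160L, 340L)),
               cds = c(131L, 310L))
  structure(list(
    chrom = "manual1", sequence = seq, genes = list(geneA = gene),
    regulatory = data.frame(chrom = "manual1", start = 6000L, end = 6100L,
                            name = "regA", stringsAsFactors = FALSE),
    tf_sites = data.frame(chrom = "manual1", start = 6010L, end = 6030L,
                          name = "tfA", stringsAsFactors = FALSE),
    length = L, seed = 4711L), class = "genome_fixture")
}

# mirror of a fixture: reverse-complemented sequence with all coordinates
# reflected, used for the strand-correctness property
mirror_fixture <- function(fx) {
  L <- fx$length
  refl <- function(a, b) c(L - b + 1L, L - a + 1L)
  genes <- lapply(fx$genes, function(g) {
    ex <- t(vapply(seq_len(nrow(g$exons)), function(i) {
      refl(g$exons[i, 1L], g$exons[i, 2L])
    }, numeric(2)))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    colnames(ex) <- c("start", "end")
    list(gene_id = g$gene_id,
         strand = if (g$strand == "+") "-" else "+",
         tx_start = L - g$tx_end + 1L, tx_end = L - g$tx_start + 1L,
         exons = ex,
         cds = if (is.null(g$cds)) NULL else refl(g$cds[1L], g$cds[2L]))
  })
  refl_df <- function(d) {
    if (nrow(d) == 0L) return(d)
    out <- d
    out$start <- L - d$end + 1L
    out$end <- L - d$start + 1L
    out
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seqv <- rev(comp[strsplit(fx$sequence, "")[[1L]]])
  structure(list(chrom = fx$chrom, sequence = paste(seqv, collapse = ""),
                 genes = genes, regulatory = refl_df(fx$regulatory),
                 tf_sites = refl_df(fx$tf_sites), length = L,
                 seed = fx$seed), class = "genome_fixture")
}

# random annotated calls table for the filter-predicate oracle
random_calls <- function(n, seed) {
  withr::with_seed(seed, {
    dp <- sample(0:12, n, replace = TRUE)
    data.frame(
      chrom = "synth1", pos = sort(sample.int(1e6, n)), ref = "A", alt = "T",
      qual = runif(n, 0, 200), genotype = "het",
      dp = dp, alt_count = pmin(dp, sample(0:6, n, replace = TRUE)),
      rms_mq = sample(c(9.9, 10, 10.1, runif(1, 0, 60)), n, replace = TRUE),
      p_strand = sample(c(9e-5, 1e-4, runif(1)), n, replace = TRUE),
      p_baseq = sample(c(1e-101, 1e-99, runif(1)), n, replace = TRUE),
      p_mapq = sample(c(0, runif(1)), n, replace = TRUE),
      p_end = sample(c(9e-5, 1e-4, runif(1)), n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

# independently coded varFilter predicate (straight re-statement of the rules)
varfilter_oracle_keep <- function(calls, p = filter_params()) {
  calls$dp >= p$min_depth & calls$dp <= p$max_depth &
    calls$alt_count >= p$min_alt_bases &
    calls$rms_mq >= p$min_rms_mq &
    calls$p_strand >= p$p_strand & calls$p_baseq >= p$p_baseq &
    calls$p_mapq >= p$p_mapq & calls$p_end >= p$p_end
}

# brute-force alignment oracle via Biostrings (independent of the C++ path):
# best mismatch count over every placement on both strands, lowest
# coordinate on ties, '+' preferred at equal coordinate
brute_map <- function(genome, read) {
  g <- Biostrings::DNAString(genome)
  L <- nchar(read)
  starts <- seq_len(nchar(genome) - L + 1L)
  mm_f <- Biostrings::neditStartingAt(Biostrings::DNAString(read), g,
                                      starting.at = starts,
                                      with.indels = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  mm_r <- Biostrings::neditStartingAt(Biostrings::DNAString(rc), g,
                                      starting.at = starts,
                                      with.indels = FALSE)
  best <- min(mm_f, mm_r)
  pos_f <- starts[mm_f == best]
  pos_r <- starts[mm_r == best]
  if (length(pos_f) && (!length(pos_r) || min(pos_f) <= min(pos_r))) {
    list(pos = min(pos_f), strand = "+", mismatches = best)
  } else {
    list(pos = min(pos_r), strand = "-", mismatches = best)
  }
}

# pure-R fusion-scanner oracle: same support rule, character-vector arithmetic
scan_oracle <- function(reads, junctions, min_overhang = 10L,
                        min_identity = 0.95) {
  jseq_chars <- lapply(junctions$sequence, function(s) strsplit(s, "")[[1L]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  support <- setNames(vector("list", nrow(junctions)), junctions$id)
  for (i in seq_len(nrow(reads))) {
    rchars <- strsplit(reads$seq[i], "")[[1L]]
    rcchars <- rev(unname(comp[rchars]))
    L <- length(rchars)
    best_mm <- Inf; best_j <- NA_character_; tie <- FALSE
    for (j in seq_len(nrow(junctions))) {
      jc <- jseq_chars[[j]]
      nS <- length(jc)
      if (L > nS) next
      b <- junctions$breakpoint[j]
      lo <- max(1L, b + min_overhang - L + 1L)
      hi <- min(b - min_overhang + 1L, nS - L + 1L)
      if (lo > hi) next
      mm <- Inf
      for (s in lo:hi) {
        win <- jc[s:(s + L - 1L)]
        mm <- min(mm, sum(win != rchars), sum(win != rcchars))
      }
      if (1 - mm / L < min_identity) next
      if (mm < best_mm) { best_mm <- mm; best_j <- junctions$id[j]; tie <- FALSE }
      else if (mm == best_mm) tie <- TRUE
    }
    if (is.finite(best_mm) && !tie) {
      support[[best_j]] <- c(support[[best_j]], reads$qname[i])
    }
  }
  vapply(support, function(x) length(unique(x)), integer(1))
}

# draw-level enumeration of the hypergeometric upper tail: every n-subset of
# a universe of N genes with K marked, counting overlaps >= k
hypergeom_enum <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # first K elements are the pathway
  mean(hits >= k)
}

small_trio_fixture <- function(seed = 202L, err_rate = 0, tumour_fraction = 1,
                               genome_length = 50000L, n_germline = 30L,
                               n_shared = 10L, n_private = 0L, depth = 30,
                               n_genes = max(1L, genome_length %/% 15000L)) {
  g <- generate_genome(genome_length, n_genes, seed)
  truth <- implant_variants(g, n_germline, n_shared, n_private, seed + 1L,
                            tumour_fraction = tumour_fraction)
  reads <- generate_trio_reads(g, truth, depth = depth, err_rate = err_rate,
                               seed = seed + 2L)
  idx <- build_index(g)
  maps <- lapply(reads, function(r) map_sample(idx, r))
  list(genome = g, truth = truth, reads = reads, index = idx, maps = maps)
}
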