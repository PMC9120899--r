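# Over-representation analysis (ORA) of gene sets against a pathway
# database: hypergeometric upper-tail p-values, Benjamini-Hochberg
# adjustment, deterministic ranking, and the top-k intersection of two
# rankings.

#' Hypergeometric upper-tail probability
#'
#' P(overlap >= k) when drawing `n` genes from a universe of `N` containing
#' `K` pathway genes.
#'
#' @param k Observed overlap.
#' @param K Pathway size (within the universe).
#' @param n Query gene-set size.
#' @param N Universe size.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || k < 0) {
    stop("impossible hypergeometric configuration")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene set
#'
#' One result per pathway: overlap, hypergeometric p, BH q and rank.
#' Pathways are intersected with the universe; the default universe is the
#' union of all pathway genes and the query set. Ranking is by p-value with
#' lexicographic pathway-id tie-break, so results are permutation-invariant.
#'
#' @param gene_set Character vector of query genes.
#' @param pathway_db Named list of pathway gene vectors (see [read_gmt()]).
#' @param universe Optional character vector; must contain `gene_set`.
#' @return Data.frame: pathway, k, K, n, N, p, q, rank (sorted by rank).
#' @export
ora <- function(gene_set, pathway_db, universe = NULL) {
  gene_set <- unique(gene_set)
  if (is.null(universe)) {
    universe <- union(unique(unlist(pathway_db, use.names = FALSE)), gene_set)
  } else {
    universe <- unique(universe)
    if (!all(gene_set %in% universe)) {
      stop("gene_set must be a subset of the universe")
    }
  }
  N <- length(universe)
  if (N == 0L) stop("empty universe")
  n <- length(gene_set)
  res <- lapply(names(pathway_db), function(pw) {
    genes <- intersect(pathway_db[[pw]], universe)
    K <- length(genes)
    k <- length(intersect(genes, gene_set))
    data.frame(pathway = pw, k = k, K = K, n = n, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pathways common to the tops of two rankings
#'
#' Pathways present in the top-`top` of both ORA result tables, ordered by
#' summed rank.
#'
#' @param results_a,results_b Ranked ORA results ([ora()]).
#' @param top Depth of each ranking to compare.
#' @return Data.frame: pathway, rank_a, rank_b, rank_sum.
#' @export
common_pathways <- function(results_a, results_b, top = 100L) {
  ta <- head(results_a[order(results_a$rank), , drop = FALSE], top)
  tb <- head(results_b[order(results_b$rank), , drop = FALSE], top)
  common <- intersect(ta$pathway, tb$pathway)
  out <- data.frame(
    pathway = common,
    rank_a = ta$rank[match(common, ta$pathway)],
    rank_b = tb$rank[match(common, tb$pathway)],
    stringsAsFactors = FALSE)
  out$rank_sum <- out$rank_a + out$rank_b
  out <- out[order(out$rank_sum, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes most frequently mutated in glioblastoma
#'
#' The top mutated-gene panel transcribed from the study's published
#' frequency table; used as the query set for pathway analysis and as gene
#' labels in synthetic fixtures.
#' @export
gbm_top_mutated_genes <- function() {
  c("TP53", "IDH1", "PTEN", "EGFR", "H3F3A", "PIK3CA", "ATRX", "NF1",
    "BRAF", "RB1", "TERT", "PIK3R1", "CHEK2", "PDGFRA", "LRP1B", "SETD2",
    "STAG2", "HIF1A", "IRS4", "KMT2C", "MET", "APC", "AR", "ERBB2",
    "FGFR2", "NOTCH1", "KIT", "NRAS", "RAF1", "CCNE1", "JAK2", "ATM",
    "ALK", "BRCA1", "BRCA2", "MAP2K2", "CCND2", "CDK6", "GATA3", "GNAS",
    "HRAS", "JAK3", "KRAS", "SMAD4", "SMO", "STK11", "TSC1", "AKT1",
    "ARAF", "CCND1", "FBXW7", "FGFR1", "MAPK3", "MLH1", "NTRK1", "NTRK3",
    "RIT1", "ROS1")
}

#' Genes recurrently involved in glioblastoma fusions
#'
#' Unique partner genes of the druggable fusions observed in the study
#' cohort and the public-tumour re-analysis tables.
#' @export
gbm_fusion_partner_genes <- function() {
  c("BCR", "ABL1", "KDR", "PDGFRA", "NCDN", "COL1A1", "PDGFB", "NIN",
    "PDGFRB", "FGFR1", "CEP85L", "ROS1", "GOPC", "KMT2A", "FLNA", "TPM3",
    "TFG", "ALK", "MSN", "MLLT1", "AKAP9", "BRAF", "MAML2", "PLAG1",
    "KIF5B", "RET", "EWSR1", "ATF1", "RARA", "PML", "GOLGA5", "FLI1",
    "NPM1", "TENM4", "NRG1", "SDC4", "NTRK1")
}

#' Build a synthetic pathway database
#'
#' Emulates a pathway reference at desk scale: six named cancer-signalling
#' pathways containing genes from both the mutated and the fused panels,
#' plus 100 pathways overlapping only the mutated panel and 100 overlapping
#' only the fused panel (padded with synthetic filler genes). By
#' construction, the top-100 rankings of the two panels share exactly the
#' six named pathways.
#'
#' @param seed Integer seed.
#' @return Named list of pathway gene vectors.
#' @export
make_pathway_db <- function(seed = 1L) {
  mut <- gbm_top_mutated_genes()
  fus <- gbm_fusion_partner_genes()
  named <- c("ErbB signaling pathway", "VEGF signaling pathway",
             "Choline metabolism in cancer",
             "Central carbon metabolism in cancer",
             "p53 signaling pathway", "Non-small cell lung cancer")
  # several genes (e.g. PDGFRA, BRAF, ALK, ROS1) belong to both panels; the
  # single-panel pathways draw only from the disjoint remainders so that the
  # two top-100 rankings share exactly the six named pathways
  mut_only <- setdiff(mut, fus)
  fus_only <- setdiff(fus, mut)
  withr::with_seed(seed, {
    filler <- sprintf("SYN%04d", seq_len(4000L))
    db <- list()
    for (i in seq_along(named)) {
      db[[named[i]]] <- c(sample(mut, 3L), sample(fus, 3L),
                          sample(filler, 10L))
    }
    for (i in seq_len(100L)) {
      db[[sprintf("Mutated-only pathway %03d", i)]] <-
        c(mut_only[(i - 1L) %% length(mut_only) + 1L], sample(filler, 14L))
    }
    for (i in seq_len(100L)) {
      db[[sprintf("Fusion-only pathway %03d", i)]] <-
        c(fus_only[(i - 1L) %% length(fus_only) + 1L], sample(filler, 14L))
    }
    db
  })
}
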