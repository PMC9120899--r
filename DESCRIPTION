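Package: cftrio
Title: Trio Liquid-Biopsy Analysis of Plasma Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale, fully reproducible pipeline for liquid-biopsy
    analysis of plasma cell-free DNA (cfDNA) in glioblastoma: fragment-length
    mixture profiling (apoptotic mono-/di-nucleosome versus long necrotic
    fragments) and cohort concentration comparison; trio
    (germline/tumour/cfDNA) single-nucleotide somatic variant calling from
    pileup genotype likelihoods with varFilter-style filtering, germline
    subtraction and tumour-cfDNA intersection; consequence and impact
    annotation of shared somatic variants against gene models; split-read
    detection of chimera-junction gene fusions with decoy-based false
    discovery control and druggable-fusion annotation; and hypergeometric
    pathway over-representation with top-ranked intersection of mutated and
    fused gene sets. A deterministic synthetic-data generator with known
    ground truth (mini-genome, implanted variants, fusion-spanning reads,
    nucleosome-sized fragment mixtures, cohort concentrations) supports
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    fgsea,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    tools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
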