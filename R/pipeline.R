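# End-to-end wiring of all stages on synthetic data: one call generates a
# cohort, maps the trio, calls and annotates somatic variants, scans for
# fusions, runs the pathway comparison, and writes a TSV report. The R
# functions themselves are the pipeline's interface; run_demo() is the
# one-command composition.

#' Pipeline configuration with defaults
#'
#' All tunables in one flat list. Unknown keys are rejected wherever a
#' config is consumed.
#'
#' @param ... Overrides of the defaults.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genome_length = 60000L, n_genes = 5L,
    n_germline = 40L, n_shared = 10L, n_private = 4L,
    depth = 30, read_len = 100L, err_rate = 0.005,
    tumour_fraction = 0.4, weights = c(0.85, 0.10, 0.05),
    k = 15L, max_mismatch_frac = 0.05,
    min_support = 10L, max_fdr = 0.05, min_reads = 5L, min_qual = 20,
    top = 100L, n_gbm = 25L, n_control = 25L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

write_report_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full demonstration pipeline on synthetic data
#'
#' Generates a mini-genome with implanted variants and fusions, simulates
#' the trio and a cohort, and runs every stage: mapping, fragment profiling,
#' trio somatic calling, consequence annotation, fusion scanning with decoy
#' FDR and drug annotation, and the two-panel pathway comparison. All
#' outputs are TSV/VCF/FASTA text files under `outdir`; identical seeds give
#' identical files.
#'
#' @param seed Integer seed driving every stage.
#' @param outdir Writable output directory (created if absent).
#' @param config A [pipeline_config()] or override list.
#' @return Invisibly, a list with the stage results and a `report` table.
#' @export
run_demo <- function(seed = 1L, outdir = tempfile("cftrio_demo_"),
                     config = pipeline_config()) {
  cfg <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir) || file.access(outdir, 2L) != 0L) {
    stop("output directory is not writable: ", outdir)
  }

  message("stage: simulate genome + truth")
  genome <- generate_genome(cfg$genome_length, cfg$n_genes,
                            derive_seed(seed, 101L))
  truth <- implant_variants(genome, cfg$n_germline, cfg$n_shared,
                            cfg$n_private, derive_seed(seed, 102L),
                            tumour_fraction = cfg$tumour_fraction,
                            weights = cfg$weights)
  write_fasta(data.frame(id = genome$chrom, sequence = genome$sequence),
              file.path(outdir, "genome.fa"))
  write_gff(genome$genes, genome$chrom, file.path(outdir, "genes.gff3"))
  write_bed(genome$regulatory, file.path(outdir, "regulatory.bed"))
  write_bed(genome$tf_sites, file.path(outdir, "tf_sites.bed"))
  write_truth(truth, file.path(outdir, "truth.tsv"))

  message("stage: simulate reads")
  reads <- generate_trio_reads(genome, truth, depth = cfg$depth,
                               read_len = cfg$read_len,
                               err_rate = cfg$err_rate,
                               seed = derive_seed(seed, 103L))
  fusion_ids <- c("NCDN-PDGFRA", "BCR-ABL", "CEP85L-ROS1", "KDR-PDGFRA",
                  "COL1A1-PDGFB", "NIN-PDGFRB", "FGFR1-BCR", "GOPC-ROS1",
                  "NTRK1-TPM3", "RET-KIF5B")
  jdb <- make_junction_db(fusion_ids, arm_len = cfg$read_len,
                          seed = derive_seed(seed, 104L))
  decoys <- make_decoy_junctions(jdb, seed = derive_seed(seed, 105L))
  fusion_support <- c("NCDN-PDGFRA" = 12L, "BCR-ABL" = 10L,
                      "CEP85L-ROS1" = 3L)
  fusion_reads <- generate_fusion_reads(jdb, fusion_support,
                                        read_len = cfg$read_len,
                                        err_rate = cfg$err_rate,
                                        seed = derive_seed(seed, 106L))
  reads$cfdna <- rbind(reads$cfdna, fusion_reads)

  message("stage: map trio")
  index <- build_index(genome, k = cfg$k)
  maps <- lapply(reads, function(r) {
    map_sample(index, r, max_mismatch_frac = cfg$max_mismatch_frac)
  })

  message("stage: fragment profile + cohort concentrations")
  frag_lengths <- lengths_from_sam(maps$cfdna$sam)
  profile <- profile_lengths(frag_lengths)
  conc <- generate_concentrations(
    cohort_config(n_gbm = cfg$n_gbm, n_control = cfg$n_control),
    seed = derive_seed(seed, 107L))
  conc_test <- compare_concentrations(conc$gbm, conc$control)
  write_report_tsv(
    data.frame(window = names(profile$fractions),
               fraction = as.numeric(profile$fractions)),
    file.path(outdir, "fragment_profile.tsv"))

  message("stage: trio somatic calling")
  trio <- call_trio(genome, maps$germline$sam, maps$tumour$sam,
                    maps$cfdna$sam, min_qual = cfg$min_qual)
  shared_ann <- annotate_variants(trio$shared, genome)
  ev <- evaluate_against_truth(shared_ann, truth)
  write_vcf(as_vcf_records(shared_ann),
            file.path(outdir, "shared_somatic.vcf"))
  ctab <- consequence_table(shared_ann$csq)
  write_report_tsv(ctab, file.path(outdir, "consequence_table.tsv"))
  write_report_tsv(shared_position_report(shared_ann, cfg$min_reads),
                   file.path(outdir, "shared_positions_by_gene.tsv"))

  message("stage: fusion scan")
  support <- scan_unmapped(maps$cfdna$unmapped, jdb)
  decoy_support <- scan_unmapped(maps$cfdna$unmapped, decoys)
  fusions <- annotate_druggable(
    call_fusions(support, decoy_support, min_support = cfg$min_support,
                 max_fdr = cfg$max_fdr))
  fus_out <- fusions
  fus_out$drugs <- vapply(fus_out$drugs, paste, character(1), collapse = ";")
  write_report_tsv(fus_out, file.path(outdir, "fusion_calls.tsv"))

  message("stage: pathway comparison")
  pdb <- make_pathway_db(seed = derive_seed(seed, 108L))
  res_mut <- ora(gbm_top_mutated_genes(), pdb)
  res_fus <- ora(gbm_fusion_partner_genes(), pdb)
  common <- common_pathways(res_mut, res_fus, top = cfg$top)
  write_report_tsv(common, file.path(outdir, "common_pathways.tsv"))

  report <- data.frame(
    metric = c("mono_fraction", "di_fraction", "necrotic_fraction",
               "concentration_t", "concentration_p",
               "n_truth_shared", "n_shared_called", "sensitivity",
               "precision", "n_fusions_called", "n_fusions_passed",
               "n_common_pathways"),
    value = c(round(profile$fractions[["mono"]], 4),
              round(profile$fractions[["di"]], 4),
              round(profile$fractions[["necrotic"]], 4),
              round(conc_test$t, 4), signif(conc_test$p, 4),
              sum(truth$variants$class == "shared"), nrow(shared_ann),
              round(ev$sensitivity, 4), round(ev$precision, 4),
              nrow(fusions), sum(fusions$passed), nrow(common)),
    stringsAsFactors = FALSE)
  write_report_tsv(report, file.path(outdir, "report.tsv"))
  message("demo complete: ", outdir)

  invisible(list(genome = genome, truth = truth, profile = profile,
                 concentrations = conc_test, trio = trio,
                 shared = shared_ann, evaluation = ev, fusions = fusions,
                 common_pathways = common, report = report,
                 outdir = outdir))
}
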