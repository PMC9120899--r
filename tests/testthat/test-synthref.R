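test_that("genome generation is deterministic and respects gene bounds", {
  g0 <- generate_genome(2000, 0, 1)
  expect_equal(nchar(g0$sequence), 2000L)
  expect_length(g0$genes, 0L)

  g1 <- generate_genome(50000, 4, 7)
  g2 <- generate_genome(50000, 4, 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fasta(data.frame(id = g1$chrom, sequence = g1$sequence),
              file.path(d1, "g.fa"))
  write_fasta(data.frame(id = g2$chrom, sequence = g2$sequence),
              file.path(d2, "g.fa"))
  write_gff(g1$genes, g1$chrom, file.path(d1, "g.gff3"))
  write_gff(g2$genes, g2$chrom, file.path(d2, "g.gff3"))
  write_bed(g1$regulatory, file.path(d1, "g.bed"))
  write_bed(g2$regulatory, file.path(d2, "g.bed"))
  for (f in c("g.fa", "g.gff3", "g.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # every exon interval within genome bounds, exons sorted/non-overlapping,
  # CDS inside the exon union, verified exhaustively
  g3 <- generate_genome(500000, 20, 7)
  expect_length(g3$genes, 20L)
  for (gene in g3$genes) {
    ex <- gene$exons
    expect_true(all(ex >= 1 & ex <= g3$length))
    expect_true(all(ex[, 1] <= ex[, 2]))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] > ex[-nrow(ex), 2]))
    if (!is.null(gene$cds)) {
      exonic <- unlist(apply(ex, 1, function(r) r[1]:r[2], simplify = FALSE))
      expect_true(all(gene$cds %in% exonic))
      cds_len <- sum(exonic >= gene$cds[1] & exonic <= gene$cds[2])
      expect_equal(cds_len %% 3L, 0L)
    }
  }
  expect_error(generate_genome(5000, 2, 1), "packing")
})

test_that("implanted variants match the genome, stay disjoint and keep their spacing", {
  g <- generate_genome(100000, 5, 3)
  t0 <- implant_variants(g, 0, 0, 0, 5)
  expect_equal(nrow(t0$variants), 0L)

  for (s in 1:5) {
    tr <- implant_variants(g, 200, 50, 20, s)
    v <- tr$variants
    expect_equal(nrow(v), 270L)
    expect_false(anyDuplicated(v$pos) > 0)
    expect_true(all(substring(g$sequence, v$pos, v$pos) == v$ref))
    expect_true(all(v$alt != v$ref))
    expect_gte(min(diff(sort(v$pos))), 150L)
    expect_setequal(unique(v$class),
                    c("germline", "shared", "tumour_only", "cfDNA_only"))
  }
  expect_error(implant_variants(g, 400, 200, 0, 1), "infeasible")
})

test_that("fragment-length mixture recovers its component weights", {
  l1 <- generate_fragment_lengths(1000, c(1, 0, 0), seed = 2)
  expect_true(all(l1 >= 50 & l1 <= 300))

  l <- generate_fragment_lengths(100000, seed = 1)
  pr <- profile_lengths(l)
  expect_lt(abs(pr$fractions[["mono"]] - 0.85), 0.01)
  expect_lt(abs(pr$fractions[["di"]] - 0.10), 0.01)
  expect_lt(abs(pr$fractions[["necrotic"]] - 0.05), 0.01)

  # arbitrary simplex weights are recovered by the window decomposition
  l2 <- generate_fragment_lengths(100000, c(0.5, 0.3, 0.2), seed = 9)
  pr2 <- profile_lengths(l2)
  expect_true(all(abs(pr2$fractions[c("mono", "di", "necrotic")] -
                        c(0.5, 0.3, 0.2)) < 0.01))
  expect_error(generate_fragment_lengths(0, seed = 1), "positive")
  expect_error(generate_fragment_lengths(10, c(0.9, 0.2, 0), seed = 1),
               "sum to 1")
})

test_that("trio reads carry variants at the designed dosages and conserve coverage", {
  g <- generate_genome(30000, 2, 21)
  tr <- implant_variants(g, 20, 6, 0, 22, tumour_fraction = 1)
  reads <- generate_trio_reads(g, tr, depth = 30, err_rate = 0, seed = 23)

  # coverage conservation within 5%
  for (smp in reads) {
    emitted <- sum(nchar(smp$seq))
    expect_equal(emitted / g$length, 30, tolerance = 0.05)
  }

  # tumour pileup alt fraction ~0.5 at a shared het site (tumour_fraction 1)
  idx <- build_index(g)
  ms <- map_sample(idx, reads$tumour)
  shared <- tr$variants[tr$variants$class == "shared", ]
  pu <- build_pileup(ms$sam[ms$sam$pos > shared$pos[1] - 150 &
                             ms$sam$pos <= shared$pos[1], ], g)
  col <- pu[[as.character(shared$pos[1])]]
  vaf <- mean(col$obs$base == shared$alt[1])
  expect_gt(vaf, 0.2)   # binomial tolerance around 0.5
  expect_lt(vaf, 0.8)

  # germline sample never carries somatic alleles when err_rate = 0
  msg <- map_sample(idx, reads$germline)
  pug <- build_pileup(msg$sam[msg$sam$pos > shared$pos[1] - 150 &
                               msg$sam$pos <= shared$pos[1], ], g)
  colg <- pug[[as.character(shared$pos[1])]]
  expect_equal(sum(colg$obs$base == shared$alt[1]), 0L)

  # byte-level determinism
  r2 <- generate_trio_reads(g, tr, depth = 30, err_rate = 0, seed = 23)
  expect_identical(reads, r2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads$cfdna, f1)
  write_fastq(r2$cfdna, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generate_trio_reads(g, tr, depth = 0, seed = 1), "depth")
  expect_error(generate_trio_reads(g, tr, err_rate = 0.5, seed = 1),
               "err_rate")
})

test_that("fusion reads span their breakpoints, come in exact counts and stay unmapped", {
  jdb <- make_junction_db(c("J-A", "K-B", "L-C"), arm_len = 100, seed = 31)
  fr <- generate_fusion_reads(jdb, c("J-A" = 10L, "K-B" = 3L),
                              read_len = 100, err_rate = 0, seed = 32)
  expect_equal(nrow(fr), 13L)
  expect_equal(sum(grepl("^fus_JA", fr$qname)), 10L)
  expect_equal(sum(grepl("^fus_KB", fr$qname)), 3L)

  # every read is an exact junction substring (possibly reverse-complemented)
  # whose window covers the breakpoint with >= 10 bases each side
  for (i in seq_len(nrow(fr))) {
    jid <- if (grepl("JA", fr$qname[i])) "J-A" else "K-B"
    jseq <- jdb$sequence[jdb$id == jid]
    hit <- regexpr(fr$seq[i], jseq, fixed = TRUE)
    if (hit < 0) {
      hit <- regexpr(cftrio:::revcomp(fr$seq[i]), jseq, fixed = TRUE)
    }
    expect_gte(hit, 1)
    s <- as.integer(hit)
    b <- jdb$breakpoint[jdb$id == jid]
    expect_lte(s, b - 10 + 1)
    expect_gte(s + 100 - 1, b + 10)
  }

  expect_error(generate_fusion_reads(jdb, c(UNKNOWN = 2L), seed = 1),
               "unknown junction")

  # none of the 13 reads map to an unrelated fixture genome
  g <- generate_genome(30000, 2, 33)
  idx <- build_index(g)
  ms <- map_sample(idx, fr)
  expect_equal(nrow(ms$sam), 0L)
  expect_equal(nrow(ms$unmapped), 13L)
})

test_that("cohort concentrations follow the configured truncated normals", {
  c0 <- generate_concentrations(cohort_config(gbm_sd = 0, control_sd = 0),
                                seed = 1)
  expect_true(all(c0$gbm == 22.6))
  expect_true(all(c0$control == 1.4))

  big <- generate_concentrations(cohort_config(n_gbm = 10000,
                                               n_control = 10000), seed = 2)
  expect_equal(mean(big$gbm), 22.6, tolerance = 0.2 / 22.6)
  expect_equal(mean(big$control), 1.4, tolerance = 0.2 / 1.4)
  expect_true(all(big$control >= 0.01))

  # the patient/control separation reproduces at default cohort sizes
  p <- vapply(1:200, function(s) {
    cc <- generate_concentrations(cohort_config(), seed = s)
    compare_concentrations(cc$gbm, cc$control)$p
  }, numeric(1))
  expect_gte(mean(p < 1e-4), 0.99)

  expect_error(cohort_config(gbm_mean = -1), "positive")
})
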