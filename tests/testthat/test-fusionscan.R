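test_that("junction databases load with validated breakpoints", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">KDR-PDGFRA|bp=60", strrep("ACGT", 30)), tf)
  db <- load_junction_db(tf)
  expect_equal(db$id, "KDR-PDGFRA")
  expect_equal(db$breakpoint, 60L)
  expect_equal(db$source, "target")

  # fixture of 20 junctions: offsets equal a manual parse of the headers
  jdb <- make_junction_db(sprintf("G%02d-H%02d", 1:20, 1:20), seed = 111)
  tf2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(junction_fasta_records(jdb), tf2)
  back <- load_junction_db(tf2)
  manual <- as.integer(sub("^.*\\|bp=([0-9]+)$", "\\1", read_fasta(tf2)$id))
  expect_equal(back$breakpoint, manual)
  expect_equal(back$sequence, jdb$sequence)

  writeLines(c(">a|bp=5", "ACGTACGTAC", ">a|bp=5", "ACGTACGTAC"), tf)
  expect_error(load_junction_db(tf), "duplicate")
  writeLines(c(">nooffset", "ACGTACGTAC"), tf)
  expect_error(load_junction_db(tf), "breakpoint offset")
  writeLines(c(">a|bp=99", "ACGTACGTAC"), tf)
  expect_error(load_junction_db(tf), "outside")
})

test_that("decoys are shuffled re-pairings matched in size and length", {
  jdb <- make_junction_db(sprintf("A%02d-B%02d", 1:10, 1:10), seed = 112)
  dec <- make_decoy_junctions(jdb, seed = 113)
  expect_equal(nrow(dec), nrow(jdb))
  expect_true(all(dec$source == "decoy"))
  expect_true(all(startsWith(dec$id, "DECOY:")))
  expect_equal(sort(nchar(dec$sequence)), sort(nchar(jdb$sequence)))
  expect_false(any(sub("^DECOY:", "", dec$id) %in% jdb$id))
})

test_that("breakpoint-spanning support obeys the overhang and identity rules", {
  jdb <- make_junction_db(c("J-X", "K-Y"), arm_len = 100, seed = 114)
  b <- jdb$breakpoint[1]
  centred <- substring(jdb$sequence[1], b - 49, b + 50)
  r1 <- data.frame(qname = "r1", mate = NA_integer_, seq = centred,
                   qual = strrep("D", 100), stringsAsFactors = FALSE)
  s <- scan_unmapped(r1, jdb)
  expect_equal(unname(s["J-X"]), 1L)
  expect_equal(unname(s["K-Y"]), 0L)

  # only 5 bases past the breakpoint: under the 10-base overhang, no support
  short <- data.frame(qname = "r2", mate = NA_integer_,
                      seq = substring(jdb$sequence[1], b - 94, b + 5),
                      qual = strrep("D", 100), stringsAsFactors = FALSE)
  expect_equal(sum(scan_unmapped(short, jdb)), 0L)

  # a read below the identity floor is not counted (21 forced mismatches)
  noisy <- centred
  substr(noisy, 1, 10) <- chartr("ACGT", "TGCA", substring(noisy, 1, 10))
  substr(noisy, 90, 100) <- chartr("ACGT", "TGCA", substring(noisy, 90, 100))
  rn <- data.frame(qname = "r3", mate = NA_integer_, seq = noisy,
                   qual = strrep("D", 100), stringsAsFactors = FALSE)
  expect_equal(sum(scan_unmapped(rn, jdb)), 0L)

  # mates of one fragment count once per junction
  pair <- data.frame(qname = c("f", "f"), mate = c(1L, 2L),
                     seq = c(centred, cftrio:::revcomp(centred)),
                     qual = strrep("D", 100), stringsAsFactors = FALSE)
  expect_equal(unname(scan_unmapped(pair, jdb)["J-X"]), 1L)
})

test_that("scanner agrees with a brute-force oracle and is monotone in its guards", {
  jdb <- make_junction_db(sprintf("P%02d-Q%02d", 1:20, 20:1), arm_len = 80,
                          seed = 115)
  withr::with_seed(118, {
    support_req <- setNames(sample(0:6, 20, replace = TRUE), jdb$id)
  })
  support_req <- support_req[support_req > 0]
  reads <- generate_fusion_reads(jdb, support_req, read_len = 60,
                                 err_rate = 0.01, seed = 116)
  withr::with_seed(117, {
    junk <- data.frame(
      qname = sprintf("junk%02d", 1:30), mate = NA_integer_,
      seq = vapply(1:30, function(i) {
        paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
      }, character(1)), qual = strrep("D", 60), stringsAsFactors = FALSE)
  })
  pool <- rbind(reads, junk)
  got <- suppressMessages(scan_unmapped(pool, jdb))
  want <- scan_oracle(pool, jdb)
  expect_equal(unname(got), unname(want), ignore_attr = TRUE)
  expect_equal(names(got), names(want))
  # implanted support is recovered exactly at this error rate
  expect_equal(got[names(support_req)], support_req)
  # conservation: total support never exceeds the fragment count
  expect_lte(sum(got), length(unique(pool$qname)))

  # lowering the identity floor never removes support
  loose <- suppressMessages(scan_unmapped(pool, jdb, min_identity = 0.80))
  expect_true(all(loose >= got))
})

test_that("fusion calling applies the 10-read floor and decoy FDR", {
  support <- c("J-X" = 10L, "K-Y" = 9L, "L-Z" = 0L)
  decoys <- setNames(rep(0L, 20), sprintf("DECOY:D%02d", 1:20))
  calls <- call_fusions(support, decoys)
  expect_equal(calls$junction, "J-X")  # 9 reads is not a candidate
  expect_true(calls$passed)
  expect_equal(calls$fdr, 0)

  # a decoy reaching the floor drives the FDR estimate over budget
  decoys["DECOY:D01"] <- 12L
  calls2 <- call_fusions(support, decoys)
  expect_false(calls2$passed)
  expect_equal(calls2$fdr, 1)

  # raising min_support never adds calls
  expect_lte(nrow(call_fusions(support, decoys, min_support = 12L)),
             nrow(calls2))

  nodec <- call_fusions(support, integer(0))
  expect_true(is.na(nodec$fdr))
  expect_equal(nodec$note, "fdr_undefined_no_decoys")
})

test_that("drug annotation reproduces the cohort drug table exactly", {
  calls <- data.frame(junction = c("BCR-ABL", "CEP85L-ROS1", "NOVEL-FUS",
                                   "BCR-ABL1"),
                      support = c(12L, 11L, 10L, 15L),
                      stringsAsFactors = FALSE)
  ann <- annotate_druggable(calls)
  expect_equal(ann$drugs[[1]], c("imatinib", "sunitinib", "sorafenib"))
  expect_equal(ann$drugs[[2]], c("crizotinib", "entrectinib", "larotrectinib"))
  expect_equal(ann$drugs[[3]], character(0))
  expect_equal(ann$flag[3], "no_known_drug")
  # alias: BCR-ABL1 resolves to the tabulated BCR-ABL row
  expect_equal(ann$drugs[[4]], ann$drugs[[1]])
})

test_that("cohort frequencies match the packaged 25-sample table", {
  freq <- cohort_fusion_frequency(table4_cohort())
  f <- setNames(freq$frequency, freq$fusion)
  expect_equal(unname(f["NCDN-PDGFRA"]), 0.40)
  expect_equal(unname(f["BCR-ABL"]), 0.08)
  expect_equal(unname(f["COL1A1-PDGFB"]), 0.08)
  expect_equal(unname(f["NIN-PDGFRB"]), 0.08)
  expect_equal(unname(f["FGFR1-BCR"]), 0.04)
  # the three fusion-free samples stay in the denominator
  expect_equal(length(unique(table4_cohort()$sample)), 25L)

  one <- cohort_fusion_frequency(list(s1 = "A-B"))
  expect_equal(one$frequency, 1)
})
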