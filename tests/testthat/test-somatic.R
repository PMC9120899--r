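make_column <- function(ref, bases, bq = 40L, mq = 60L,
                        rev = rep(FALSE, length(bases)),
                        end_dist = rep(25L, length(bases)), pos = 1000L) {
  list(chrom = "synth1", pos = pos, ref = ref,
       obs = data.frame(base = bases, bq = bq, mq = mq, rev = rev,
                        end_dist = end_dist, stringsAsFactors = FALSE))
}

test_that("pileup columns cover exactly the aligned bases", {
  g <- generate_genome(2000, 0, 61)
  sam <- data.frame(qname = "r", flag = 0L, rname = g$chrom, pos = 1L,
                    mapq = 60L, cigar = "100M", rnext = "*", pnext = 0L,
                    tlen = 0L, seq = substring(g$sequence, 1, 100),
                    qual = strrep("D", 100), nm = 0L,
                    stringsAsFactors = FALSE)
  pu <- build_pileup(sam, g)
  expect_length(pu, 100L)
  expect_equal(as.integer(names(pu)), 1:100)
  expect_true(all(vapply(pu, function(c) nrow(c$obs), integer(1)) == 1L))
  expect_equal(pu[["37"]]$ref, substring(g$sequence, 37, 37))
  expect_length(build_pileup(empty_sam(), g), 0L)

  # depth equals brute-force interval stabbing for random reads
  withr::with_seed(62, {
    n <- 200
    s <- sample.int(g$length - 99L, n, replace = TRUE)
  })
  sam2 <- data.frame(qname = sprintf("r%03d", 1:n), flag = 0L,
                     rname = g$chrom, pos = s, mapq = 60L, cigar = "100M",
                     rnext = "*", pnext = 0L, tlen = 0L,
                     seq = substring(g$sequence, s, s + 99L),
                     qual = strrep("D", 100), nm = 0L,
                     stringsAsFactors = FALSE)
  pu2 <- build_pileup(sam2, g)
  depth <- vapply(pu2, function(c) nrow(c$obs), integer(1))
  stab <- vapply(as.integer(names(pu2)), function(p) {
    sum(s <= p & s + 99L >= p)
  }, integer(1))
  expect_equal(unname(depth), stab)
})

test_that("genotype likelihoods call hets and stay silent on reference columns", {
  col <- make_column("A", c(rep("A", 15), rep("T", 15)))
  call <- genotype_call(col)
  expect_equal(call$genotype, "het")
  expect_equal(call$alt, "T")
  expect_gt(call$qual, 100)
  expect_equal(call$dp, 30L)
  expect_equal(call$alt_count, 15L)
  expect_equal(call$rms_mq, 60)

  # closed-form likelihood check: QUAL = 10log10((L1+L2)/L0)
  e <- 1e-4
  l0 <- 15 * log(1 - e) + 15 * log(e / 3)
  l1 <- 30 * log(0.5 * (1 - e) + 0.5 * e / 3)
  l2 <- 15 * log(e / 3) + 15 * log(1 - e)
  q_exp <- 10 / log(10) *
    (cftrio:::logsumexp(c(l1, l2)) - l0)
  expect_equal(call$qual, q_exp, tolerance = 1e-8)

  expect_null(genotype_call(make_column("A", rep("A", 30))))
  expect_null(genotype_call(make_column("A", rep("N", 5))))

  one <- genotype_call(make_column("A", "T"))
  expect_equal(one$dp, 1L)
  expect_equal(one$alt_count, 1L)

  hom <- genotype_call(make_column("G", rep("C", 30)))
  expect_equal(hom$genotype, "hom-alt")
})

test_that("PV4 quartet matches exact Fisher enumeration and is neutral under symmetry", {
  bal <- make_column("A", c(rep("A", 10), rep("T", 10)),
                     rev = rep(c(FALSE, TRUE), 10))
  expect_equal(compute_bias_pvalues(bal, "T")[1], 1)

  skew <- make_column("A", c(rep("A", 10), rep("T", 10)),
                      rev = c(rep(FALSE, 10), rep(TRUE, 10)))
  p_strand <- compute_bias_pvalues(skew, "T")[1]
  d <- dhyper(0:10, 10, 10, 10)
  p_enum <- sum(d[d <= d[11] * (1 + 1e-7)])
  expect_equal(p_strand, p_enum, tolerance = 1e-9)

  # identical quality distributions: no shift, p >= 0.5
  same_q <- compute_bias_pvalues(bal, "T")
  expect_gte(same_q[2], 0.5)
  expect_gte(same_q[3], 0.5)

  # one-sided columns return the neutral quartet
  expect_equal(compute_bias_pvalues(make_column("A", rep("T", 5)), "T"),
               c(1, 1, 1, 1))
})

test_that("var_filter applies the printed defaults with first-fail reasons", {
  calls <- random_calls(4, 71)
  calls$dp <- c(1L, 30L, 30L, 30L)
  calls$alt_count <- c(1L, 15L, 15L, 15L)
  calls$rms_mq <- c(60, 9.9, 10, 60)
  calls[, c("p_strand", "p_baseq", "p_mapq", "p_end")] <- 0.5
  res <- var_filter(calls)
  expect_equal(res$removed$reason, c("min_depth", "min_rms_mq"))
  expect_equal(res$kept$pos, calls$pos[3:4])  # RMS MQ == 10 is kept
  expect_true(all(res$kept$filter == "PASS"))

  calls2 <- random_calls(3, 72)
  calls2$dp <- 30L
  calls2$alt_count <- 15L
  calls2$rms_mq <- 60
  calls2[, c("p_baseq", "p_mapq")] <- 0.5
  calls2$p_strand <- c(9e-5, 0.5, 0.5)
  calls2$p_end <- c(9e-5, 9e-5, 0.5)
  res2 <- var_filter(calls2)
  expect_equal(res2$removed$reason, c("p_strand", "p_end"))
  expect_equal(res2$kept$pos, calls2$pos[3])

  # missing annotation removes with reason "unannotated"
  calls3 <- random_calls(2, 73)
  calls3$rms_mq[1] <- NA
  res3 <- var_filter(calls3)
  expect_true("unannotated" %in% res3$removed$reason)
})

test_that("var_filter equals an independently coded predicate on 1000 random calls", {
  calls <- random_calls(1000, 74)
  res <- var_filter(calls)
  keep <- varfilter_oracle_keep(calls)
  expect_equal(res$kept$pos, calls$pos[keep])
  expect_equal(nrow(res$kept) + nrow(res$removed), 1000L)

  # monotonicity: tightening any threshold never grows the kept set
  tighter <- list(filter_params(min_depth = 4),
                  filter_params(min_alt_bases = 3),
                  filter_params(min_rms_mq = 30),
                  filter_params(p_strand = 1e-2),
                  filter_params(p_end = 1e-2))
  for (p in tighter) {
    kt <- var_filter(calls, p)$kept
    expect_true(all(kt$pos %in% res$kept$pos))
  }
})

test_that("germline subtraction and somatic intersection obey set algebra", {
  mk <- function(pos, alt = "T") {
    data.frame(chrom = "synth1", pos = as.integer(pos), ref = "A", alt = alt,
               qual = 100, genotype = "het", dp = 30L, alt_count = 15L,
               rms_mq = 60, p_strand = 1, p_baseq = 1, p_mapq = 1, p_end = 1,
               stringsAsFactors = FALSE)
  }
  a <- mk(c(100, 200, 300))
  g <- mk(c(200, 400))
  expect_equal(nrow(subtract_germline(a, a)), 0L)
  expect_equal(subtract_germline(a, mk(c(700, 900)))$pos, a$pos)
  expect_equal(subtract_germline(a, g)$pos, c(100L, 300L))
  # matching is on the full allele key, not position alone
  expect_equal(subtract_germline(a, mk(200, alt = "G"))$pos, a$pos)
  expect_error(subtract_germline(a[c(2, 1, 3), ], g), "sorted")

  b <- mk(c(200, 300, 500))
  i1 <- intersect_somatic(a, b)
  expect_equal(i1$pos, c(200L, 300L))
  expect_true(all(c("cfdna_dp", "cfdna_qual") %in% names(i1)))
  expect_equal(nrow(intersect_somatic(a, mk(999))), 0L)
  expect_equal(intersect_somatic(a, a)$pos, a$pos)

  # random sets equal the set oracles
  withr::with_seed(75, {
    pa <- sort(sample.int(5000, 300))
    pg <- sort(sample.int(5000, 300))
  })
  sa <- mk(pa); sg <- mk(pg)
  expect_equal(subtract_germline(sa, sg)$pos, setdiff(pa, pg))
  expect_equal(intersect_somatic(sa, sg)$pos, intersect(pa, pg))

  # shared-position report enforces depth in both samples
  sh <- intersect_somatic(sa, sg)
  sh$cfdna_dp[1] <- 4L
  rep5 <- shared_position_report(sh, min_reads = 5L)
  expect_equal(sum(rep5$n_positions), nrow(sh) - 1L)
  rep0 <- shared_position_report(sh, min_reads = 0L)
  expect_equal(sum(rep0$n_positions), nrow(sh))
})

test_that("truth evaluation computes sensitivity and precision ratios", {
  g <- generate_genome(100000, 2, 81)
  truth <- implant_variants(g, 0, 20, 0, 82)
  tv <- truth$variants
  mk <- function(d) data.frame(chrom = d$chrom, pos = d$pos, ref = d$ref,
                               alt = d$alt, stringsAsFactors = FALSE)
  full <- evaluate_against_truth(mk(tv), truth)
  expect_equal(full$sensitivity, 1)
  expect_equal(full$precision, 1)
  half <- evaluate_against_truth(mk(tv[1:10, ]), truth)
  expect_equal(half$sensitivity, 0.5)
  expect_equal(half$precision, 1)
  noisy <- mk(tv[1:10, ])
  noisy$pos <- c(tv$pos[1:5], tv$pos[6:10] + 3L)  # 5 off-target calls
  mixed <- evaluate_against_truth(noisy, truth)
  expect_equal(mixed$sensitivity, 0.25)
  expect_equal(mixed$precision, 0.5)
  expect_equal(mixed$tp + mixed$fn, 20L)
  empty_truth <- implant_variants(g, 5, 0, 0, 83)
  expect_error(evaluate_against_truth(mk(tv), empty_truth), "no shared")
})

test_that("error-free trio with full tumour fraction recovers every shared variant", {
  fx <- small_trio_fixture(seed = 202L, err_rate = 0, tumour_fraction = 1)
  trio <- suppressMessages(call_trio(
    fx$genome, fx$maps$germline$sam, fx$maps$tumour$sam, fx$maps$cfdna$sam))
  ev <- evaluate_against_truth(trio$shared, fx$truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)
  # subtraction really removed the germline component
  germ_pos <- fx$truth$variants$pos[fx$truth$variants$class == "germline"]
  expect_false(any(trio$shared$pos %in% germ_pos))
})
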