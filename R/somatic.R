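# Trio somatic SNV calling: pileup genotype likelihoods under a biallelic
# diploid model, varFilter-style rule filtering with the classical printed
# defaults, germline subtraction, and the tumour/cfDNA intersection. The
# seven-stage structure (map, pileup, call, normalise, filter, subtract,
# intersect) is preserved explicitly even where a stage is an identity for
# SNV-only data.

#' varFilter-style filtering thresholds
#'
#' Defaults are the classical varFilter defaults: minimum RMS mapping
#' quality 10, depth in [2, 1e7], at least 2 alternate bases, and PV4
#' bias p-value floors (strand 1e-4, baseQ 1e-100, mapQ 0, end-distance
#' 1e-4, HWE 1e-4). The HWE rule is a pass-through for single-sample calls
#' (no cross-sample genotype counts exist), and the gap-adjacency rules are
#' inert because indels are excluded upstream.
#'
#' @param min_rms_mq,min_depth,max_depth,min_alt_bases,p_strand,p_baseq,p_mapq,p_end,p_hwe
#'   Thresholds; a call is removed when its value falls strictly below
#'   (depth: outside) the corresponding bound.
#' @export
filter_params <- function(min_rms_mq = 10, min_depth = 2, max_depth = 1e7,
                          min_alt_bases = 2, p_strand = 1e-4,
                          p_baseq = 1e-100, p_mapq = 0, p_end = 1e-4,
                          p_hwe = 1e-4) {
  p <- list(min_rms_mq = min_rms_mq, min_depth = min_depth,
            max_depth = max_depth, min_alt_bases = min_alt_bases,
            p_strand = p_strand, p_baseq = p_baseq, p_mapq = p_mapq,
            p_end = p_end, p_hwe = p_hwe)
  if (any(unlist(p) < 0)) stop("all thresholds must be >= 0")
  p
}

#' Build a pileup from SAM records
#'
#' Pure-R reference implementation for small inputs (the genome-scale path
#' uses the compiled candidate screen inside [call_sample()]). One column per
#' covered position; indels never arise because the internal mapper is
#' ungapped. Reads overhanging the genome end are clipped with a warning.
#'
#' @param records Mapped SAM data.frame.
#' @param genome A `genome_fixture` or sequence string.
#' @return List of pileup columns: each has `chrom`, `pos`, `ref` and an
#'   `obs` data.frame (base, bq, mq, rev, end_dist).
#' @export
build_pileup <- function(records, genome) {
  gseq <- genome_sequence(genome)
  chrom <- if (inherits(genome, "genome_fixture")) genome$chrom else "ref"
  G <- nchar(gseq)
  if (nrow(records) == 0L) return(list())
  obs <- list()
  clipped <- 0L
  for (i in seq_len(nrow(records))) {
    L <- nchar(records$seq[i])
    p <- records$pos[i]
    gp <- p:(p + L - 1L)
    keep <- gp >= 1L & gp <= G
    clipped <- clipped + sum(!keep)
    j <- which(keep)
    obs[[i]] <- data.frame(
      pos = gp[j],
      base = substring(records$seq[i], j, j),
      bq = utf8ToInt(records$qual[i])[j] - 33L,
      mq = records$mapq[i],
      rev = bitwAnd(records$flag[i], 16L) > 0L,
      end_dist = pmin(j, L - j + 1L),
      stringsAsFactors = FALSE)
  }
  if (clipped > 0L) warning(clipped, " base(s) clipped at genome boundary")
  all_obs <- do.call(rbind, obs)
  split_obs <- split(all_obs, all_obs$pos)
  lapply(split_obs, function(d) {
    list(chrom = chrom, pos = d$pos[1L],
         ref = substring(gseq, d$pos[1L], d$pos[1L]),
         obs = d[, c("base", "bq", "mq", "rev", "end_dist")])
  })
}

#' Call a genotype at one pileup column
#'
#' Biallelic diploid model: for alt dosage g in \{0, 1, 2\} the likelihood
#' of an observed base b is `(1-g/2) P(b|ref) + (g/2) P(b|alt)` with
#' `P(b|a) = 1-e` when `b == a` and `e/3` otherwise, `e = 10^(-Q/10)`.
#' Log-likelihoods are summed over observations; the alternate allele is the
#' most frequent non-reference base. A call is emitted only when the
#' maximum-likelihood dosage is >= 1; QUAL is the phred-scaled posterior
#' odds against g = 0 under a uniform prior.
#'
#' @param column A pileup column (see [build_pileup()]).
#' @param min_alt_qual Minimum base quality for an observation to nominate
#'   the alternate allele (the likelihood still uses all observations).
#' @return One-row calls data.frame, or NULL when the column is reference.
#' @export
genotype_call <- function(column, min_alt_qual = 0) {
  obs <- column$obs
  obs <- obs[obs$base %in% BASES, , drop = FALSE]
  if (nrow(obs) == 0L) return(NULL)
  ref <- column$ref
  nom <- obs$base[obs$base != ref & obs$bq >= min_alt_qual]
  if (length(nom) == 0L) return(NULL)
  tab <- table(factor(nom, levels = BASES))
  alt <- names(tab)[which.max(tab)]  # ties resolve in base order
  e <- 10^(-obs$bq / 10)
  pref <- ifelse(obs$base == ref, 1 - e, e / 3)
  palt <- ifelse(obs$base == alt, 1 - e, e / 3)
  ll <- vapply(0:2, function(g) {
    sum(log((1 - g / 2) * pref + (g / 2) * palt))
  }, numeric(1))
  g <- which.max(ll) - 1L
  if (g == 0L) return(NULL)
  qual <- min(9999, 10 / log(10) * (logsumexp(ll[2:3]) - ll[1L]))
  pv4 <- compute_bias_pvalues(column, alt)
  data.frame(
    chrom = column$chrom, pos = column$pos, ref = ref, alt = alt,
    qual = qual, genotype = c("het", "hom-alt")[g],
    dp = nrow(column$obs), alt_count = as.integer(sum(obs$base == alt)),
    rms_mq = sqrt(mean(obs$mq^2)),
    p_strand = pv4[1L], p_baseq = pv4[2L], p_mapq = pv4[3L], p_end = pv4[4L],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' PV4 bias p-values for a pileup column
#'
#' Strand bias: two-sided Fisher exact test on the ref/alt x fwd/rev table.
#' Base-quality, mapping-quality and end-distance bias: two-sided
#' Mann-Whitney tests (normal approximation with tie correction) between
#' ref- and alt-supporting observations. Columns lacking either a ref or an
#' alt observation return (1, 1, 1, 1).
#'
#' @param column A pileup column.
#' @param alt The alternate allele.
#' @return Numeric vector: strand, baseQ, mapQ, end-distance p-values.
#' @export
compute_bias_pvalues <- function(column, alt) {
  obs <- column$obs
  ro <- obs[obs$base == column$ref, , drop = FALSE]
  ao <- obs[obs$base == alt, , drop = FALSE]
  if (nrow(ro) == 0L || nrow(ao) == 0L) return(c(1, 1, 1, 1))
  m <- matrix(c(sum(!ro$rev), sum(ro$rev), sum(!ao$rev), sum(ao$rev)), 2L)
  p_strand <- fisher.test(m)$p.value
  mw <- function(x, y) {
    if (length(unique(c(x, y))) < 2L) return(1)
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    if (is.na(p)) 1 else p
  }
  c(p_strand, mw(ro$bq, ao$bq), mw(ro$mq, ao$mq),
    mw(ro$end_dist, ao$end_dist))
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), genotype = character(),
             dp = integer(), alt_count = integer(), rms_mq = numeric(),
             p_strand = numeric(), p_baseq = numeric(), p_mapq = numeric(),
             p_end = numeric(), stringsAsFactors = FALSE)
}

#' Call variants across a whole sample
#'
#' Genome-scale driver: a compiled pileup pass collects full observation
#' vectors at candidate sites (>= `min_alt_screen` reads of one non-ref
#' base, mirroring the downstream minimum-alternate-bases rule), then
#' [genotype_call()] is evaluated at each candidate.
#'
#' @param records Mapped SAM data.frame.
#' @param genome A `genome_fixture` or sequence string.
#' @param min_alt_screen Candidate screen threshold.
#' @param min_alt_qual Passed to [genotype_call()].
#' @return Calls data.frame sorted by position.
#' @export
call_sample <- function(records, genome, min_alt_screen = 2L,
                        min_alt_qual = 0) {
  gseq <- genome_sequence(genome)
  chrom <- if (inherits(genome, "genome_fixture")) genome$chrom else "ref"
  if (nrow(records) == 0L) return(empty_calls())
  cand <- cpp_pileup_candidates(
    gseq, as.integer(records$pos), records$seq, records$qual,
    as.integer(records$mapq), bitwAnd(records$flag, 16L) > 0L,
    as.integer(min_alt_screen))
  if (cand$clipped > 0) {
    warning(cand$clipped, " base(s) clipped at genome boundary")
  }
  nc <- length(cand$pos)
  if (nc == 0L) return(empty_calls())
  idx <- split(seq_along(cand$obs_site), cand$obs_site)
  rows <- vector("list", nc)
  for (i in seq_len(nc)) {
    j <- idx[[as.character(i)]]
    column <- list(
      chrom = chrom, pos = cand$pos[i], ref = cand$ref[i],
      obs = data.frame(base = cand$obs_base[j], bq = cand$obs_bq[j],
                       mq = cand$obs_mq[j], rev = cand$obs_rev[j] > 0L,
                       end_dist = cand$obs_end[j], stringsAsFactors = FALSE))
    rows[[i]] <- genotype_call(column, min_alt_qual = min_alt_qual)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_calls())
  out <- do.call(rbind, rows)
  out[order(out$pos), , drop = FALSE]
}

#' Normalise called variants
#'
#' Left-alignment only affects indels, which the SNV-only pipeline excludes,
#' so this stage is an explicit identity kept to preserve the seven-stage
#' calling structure; it logs that it ran.
#'
#' @param calls Calls data.frame.
#' @export
normalize_variants <- function(calls) {
  message("normalize: identity for SNV-only records (", nrow(calls),
          " calls)")
  calls
}

call_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

check_sorted <- function(calls, what) {
  o <- order(calls$chrom, calls$pos)
  if (!identical(o, seq_len(nrow(calls)))) {
    stop(what, " calls must be sorted by (chrom, pos)")
  }
}

#' Apply varFilter-style rules
#'
#' A call is removed iff depth < min_depth, depth > max_depth, alternate
#' count < min_alt_bases, RMS mapping quality < min_rms_mq, or any PV4
#' p-value falls strictly below its floor (strand, baseQ, mapQ,
#' end-distance, then the pass-through HWE rule). Each removed call is
#' labelled with the first failing rule in that order; calls missing an
#' annotation are removed with reason "unannotated".
#'
#' @param calls Calls data.frame.
#' @param params A [filter_params()] list.
#' @return List with `kept` (calls, `filter` column set to "PASS") and
#'   `removed` (calls with a `reason` column).
#' @export
var_filter <- function(calls, params = filter_params()) {
  if (nrow(calls) == 0L) {
    return(list(kept = calls, removed = cbind(calls, reason = character(0))))
  }
  need <- c("dp", "alt_count", "rms_mq", "p_strand", "p_baseq", "p_mapq",
            "p_end")
  ann <- as.matrix(calls[, need])
  unannotated <- apply(is.na(ann), 1L, any)
  p_hwe <- if (is.null(calls$p_hwe)) rep(1, nrow(calls)) else calls$p_hwe
  reason <- rep(NA_character_, nrow(calls))
  rule <- function(bad, label) {
    ifelse(is.na(reason) & bad, label, reason)
  }
  reason <- rule(unannotated, "unannotated")
  reason <- rule(calls$dp < params$min_depth, "min_depth")
  reason <- rule(calls$dp > params$max_depth, "max_depth")
  reason <- rule(calls$alt_count < params$min_alt_bases, "min_alt_bases")
  reason <- rule(calls$rms_mq < params$min_rms_mq, "min_rms_mq")
  reason <- rule(calls$p_strand < params$p_strand, "p_strand")
  reason <- rule(calls$p_baseq < params$p_baseq, "p_baseq")
  reason <- rule(calls$p_mapq < params$p_mapq, "p_mapq")
  reason <- rule(calls$p_end < params$p_end, "p_end")
  reason <- rule(p_hwe < params$p_hwe, "p_hwe")
  keep <- is.na(reason)
  kept <- calls[keep, , drop = FALSE]
  kept$filter <- rep("PASS", nrow(kept))
  removed <- calls[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = kept, removed = removed)
}

#' Remove germline records from a sample's calls
#'
#' Keeps records of `sample_calls` whose (chrom, pos, ref, alt) key is
#' absent from `germline_calls`; records shared with the germline sample are
#' dropped from downstream analysis. Both inputs must be position-sorted.
#'
#' @param sample_calls,germline_calls Calls data.frames.
#' @export
subtract_germline <- function(sample_calls, germline_calls) {
  check_sorted(sample_calls, "sample")
  check_sorted(germline_calls, "germline")
  keep <- !(call_key(sample_calls) %in% call_key(germline_calls))
  sample_calls[keep, , drop = FALSE]
}

#' Intersect tumour and cfDNA somatic calls
#'
#' Records matching on (chrom, pos, ref, alt). Tumour-side QUAL and
#' annotations are retained; the cfDNA depth, alt count and QUAL are
#' recorded alongside.
#'
#' @param tumour_somatic,cfdna_somatic Germline-subtracted calls.
#' @export
intersect_somatic <- function(tumour_somatic, cfdna_somatic) {
  kt <- call_key(tumour_somatic)
  kc <- call_key(cfdna_somatic)
  m <- match(kt, kc)
  keep <- !is.na(m)
  out <- tumour_somatic[keep, , drop = FALSE]
  out$cfdna_dp <- cfdna_somatic$dp[m[keep]]
  out$cfdna_alt_count <- cfdna_somatic$alt_count[m[keep]]
  out$cfdna_qual <- cfdna_somatic$qual[m[keep]]
  out
}

#' Per-gene report of shared mutated positions
#'
#' Keeps shared calls with at least `min_reads` supporting depth in both
#' tumour and cfDNA, then aggregates per gene (calls must carry a `gene`
#' column from [annotate_variants()]; unannotated calls group under NA).
#'
#' @param shared_calls Output of [intersect_somatic()].
#' @param min_reads Minimum depth in each sample.
#' @export
shared_position_report <- function(shared_calls, min_reads = 5L) {
  keep <- shared_calls$dp >= min_reads & shared_calls$cfdna_dp >= min_reads
  kept <- shared_calls[keep, , drop = FALSE]
  gene <- if (is.null(kept$gene)) rep(NA_character_, nrow(kept)) else kept$gene
  gene[is.na(gene)] <- "."
  if (nrow(kept) == 0L) {
    return(data.frame(gene = character(), n_positions = integer(),
                      positions = character(), stringsAsFactors = FALSE))
  }
  agg <- tapply(kept$pos, gene, function(p) {
    c(n = length(p), pos = paste(sort(p), collapse = ","))
  }, default = NULL)
  data.frame(
    gene = names(agg),
    n_positions = vapply(agg, function(x) as.integer(x[["n"]]), integer(1)),
    positions = vapply(agg, function(x) x[["pos"]], character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Sensitivity and precision against a truth set
#'
#' Sensitivity = recovered shared truth variants / all shared truth
#' variants; precision (the study's "selectivity") = recovered shared truth
#' variants / all shared calls.
#'
#' @param called Shared somatic calls data.frame.
#' @param truth A `truth_set`.
#' @return List: `sensitivity`, `precision`, `tp`, `fp`, `fn`.
#' @export
evaluate_against_truth <- function(called, truth) {
  tv <- truth$variants[truth$variants$class == "shared", , drop = FALSE]
  if (nrow(tv) == 0L) stop("truth set contains no shared somatic variants")
  tk <- paste(tv$chrom, tv$pos, tv$ref, tv$alt, sep = ":")
  ck <- call_key(called)
  tp <- sum(ck %in% tk)
  list(sensitivity = tp / length(tk),
       precision = if (length(ck)) tp / length(ck) else NA_real_,
       tp = tp, fp = length(ck) - tp, fn = length(tk) - tp)
}

#' Run the full trio calling pipeline
#'
#' Calls each sample, applies the identity normalisation stage and the
#' varFilter rules, subtracts germline records from tumour and cfDNA, and
#' intersects the two somatic sets.
#'
#' @param genome A `genome_fixture`.
#' @param sam_germline,sam_tumour,sam_cfdna Mapped SAM data.frames.
#' @param params [filter_params()].
#' @param min_qual Minimum QUAL for a shared somatic call to be reported;
#'   the operational stand-in for call-level false-discovery control.
#' @return List of calls at each stage, including `shared`.
#' @export
call_trio <- function(genome, sam_germline, sam_tumour, sam_cfdna,
                      params = filter_params(), min_qual = 20) {
  g <- var_filter(normalize_variants(call_sample(sam_germline, genome)),
                  params)
  t <- var_filter(normalize_variants(call_sample(sam_tumour, genome)),
                  params)
  c_ <- var_filter(normalize_variants(call_sample(sam_cfdna, genome)),
                   params)
  tum_som <- subtract_germline(t$kept, g$kept)
  cf_som <- subtract_germline(c_$kept, g$kept)
  shared <- intersect_somatic(tum_som, cf_som)
  shared <- shared[shared$qual >= min_qual & shared$cfdna_qual >= min_qual, ,
                   drop = FALSE]
  list(germline = g$kept, tumour = t$kept, cfdna = c_$kept,
       tumour_somatic = tum_som, cfdna_somatic = cf_som, shared = shared,
       removed = list(germline = g$removed, tumour = t$removed,
                      cfdna = c_$removed))
}
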