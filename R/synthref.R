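# Synthetic-data generators with known ground truth: mini-genome with gene
# models and regulatory regions, implanted germline/somatic variants, trio
# paired-end reads, cfDNA fragment-length mixtures, fusion-junction-spanning
# reads, and cohort plasma concentrations. Every generator is byte-
# deterministic under a fixed seed.

BASES <- c("A", "C", "G", "T")

#' Generate a mini reference genome with gene models
#'
#' Produces a uniform-random sequence carrying `n_genes` non-overlapping gene
#' models (2-4 exons each; about 80% coding, with UTRs flanking a CDS whose
#' spliced length is a multiple of three), plus promoter-like regulatory
#' intervals and TF-binding-site intervals upstream of a subset of genes.
#'
#' @param length Genome length in bases.
#' @param n_genes Number of genes to place (each needs a 10 kb budget).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param chrom Chromosome name used in all emitted files.
#' @return A `genome_fixture`: list with `chrom`, `sequence`, `genes`,
#'   `regulatory`, `tf_sites`, `length`, `seed`.
#' @export
generate_genome <- function(length, n_genes, seed, chrom = "synth1") {
  length <- as.integer(length)
  n_genes <- as.integer(n_genes)
  if (length < 1L) stop("genome length must be positive")
  if (n_genes > 0L && length < 10000L * n_genes) {
    stop("infeasible gene packing: need at least 10 kb of genome per gene")
  }
  withr::with_seed(seed, {
    sequence <- paste(sample(BASES, length, replace = TRUE), collapse = "")
    genes <- list()
    reg <- tf <- data.frame(chrom = character(), start = integer(),
                            end = integer(), name = character(),
                            stringsAsFactors = FALSE)
    if (n_genes > 0L) {
      slot <- length %/% n_genes
      for (i in seq_len(n_genes)) {
        n_ex <- sample(2:4, 1L)
        ex_len <- sample(120:300, n_ex, replace = TRUE)
        in_len <- sample(200:800, n_ex - 1L, replace = TRUE)
        span <- sum(ex_len) + sum(in_len)
        lo <- (i - 1L) * slot + 2600L
        hi <- i * slot - 2600L - span
        start <- sample(lo:hi, 1L)
        ex_start <- integer(n_ex)
        ex_end <- integer(n_ex)
        cur <- start
        for (e in seq_len(n_ex)) {
          ex_start[e] <- cur
          ex_end[e] <- cur + ex_len[e] - 1L
          if (e < n_ex) cur <- ex_end[e] + in_len[e] + 1L
        }
        strand <- sample(c("+", "-"), 1L)
        coding <- runif(1) < 0.8
        cds <- NULL
        if (coding) {
          spliced <- unlist(lapply(seq_len(n_ex), function(e) {
            ex_start[e]:ex_end[e]
          }))
          # leave >= 30 spliced bases of UTR either side, CDS length % 3 == 0
          cds_from <- 31L
          cds_to <- base::length(spliced) - 30L
          cds_len <- ((cds_to - cds_from + 1L) %/% 3L) * 3L
          cds_to <- cds_from + cds_len - 1L
          cds <- c(spliced[cds_from], spliced[cds_to])
        }
        gid <- sprintf("gene%03d", i)
        genes[[gid]] <- list(gene_id = gid, strand = strand,
                             tx_start = start, tx_end = ex_end[n_ex],
                             exons = cbind(start = ex_start, end = ex_end),
                             cds = cds)
        if (runif(1) < 0.7) {
          # promoter-like block upstream of the TSS, strand-aware
          pr <- if (strand == "+") c(start - 2400L, start - 2100L)
                else c(ex_end[n_ex] + 2100L, ex_end[n_ex] + 2400L)
          reg <- rbind(reg, data.frame(chrom = chrom, start = pr[1L],
                                       end = pr[2L],
                                       name = paste0(gid, "_prom"),
                                       stringsAsFactors = FALSE))
          if (runif(1) < 0.5) {
            tf0 <- pr[1L] + 50L
            tf <- rbind(tf, data.frame(chrom = chrom, start = tf0,
                                       end = tf0 + 24L,
                                       name = paste0(gid, "_tfbs"),
                                       stringsAsFactors = FALSE))
          }
        }
      }
    }
    structure(list(chrom = chrom, sequence = sequence, genes = genes,
                   regulatory = reg, tf_sites = tf, length = length,
                   seed = seed),
              class = "genome_fixture")
  })
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf("genome_fixture: %s, %d bp, %d genes, %d regulatory, %d TF sites\n",
              x$chrom, x$length, length(x$genes), nrow(x$regulatory),
              nrow(x$tf_sites)))
  invisible(x)
}

genome_sequence <- function(genome) {
  if (inherits(genome, "genome_fixture")) genome$sequence else genome
}

#' Implant germline and somatic variants with known truth
#'
#' Positions are sampled one per 200 bp bin with a bounded in-bin offset, so
#' any two variants are at least 150 bp apart and a 100 bp read window never
#' carries more than one variant. The reference allele always equals the
#' genome base; alternate alleles differ from it.
#'
#' @param genome A `genome_fixture`.
#' @param n_germline,n_shared_somatic,n_private Variant counts. Private
#'   variants are split alternately between tumour-only and cfDNA-only.
#' @param seed Integer seed.
#' @param tumour_fraction Fraction of cfDNA fragments that are tumour-derived.
#' @param weights cfDNA fragment-length mixture weights (mono, di, necrotic).
#' @return A `truth_set`: list with `variants` (chrom, pos, ref, alt, class,
#'   genotype), `tumour_fraction`, `weights`, `seed`.
#' @export
implant_variants <- function(genome, n_germline, n_shared_somatic, n_private,
                             seed, tumour_fraction = 0.4,
                             weights = c(0.85, 0.10, 0.05)) {
  stopifnot(inherits(genome, "genome_fixture"))
  if (abs(sum(weights) - 1) > 1e-12) stop("mixture weights must sum to 1")
  if (tumour_fraction <= 0 || tumour_fraction > 1) {
    stop("tumour_fraction must be in (0, 1]")
  }
  total <- n_germline + n_shared_somatic + n_private
  n_bins <- genome$length %/% 200L
  if (total > n_bins) stop("variant spacing infeasible: too many variants")
  withr::with_seed(seed, {
    if (total == 0L) {
      variants <- data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             class = character(), genotype = character(),
                             stringsAsFactors = FALSE)
    } else {
      bins <- sort(sample.int(n_bins, total))
      pos <- (bins - 1L) * 200L + 1L + sample(0:49, total, replace = TRUE)
      ref <- substring(genome$sequence, pos, pos)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L),
                    character(1), USE.NAMES = FALSE)
      n_t_only <- (n_private + 1L) %/% 2L
      cls <- sample(c(rep("germline", n_germline),
                      rep("shared", n_shared_somatic),
                      rep("tumour_only", n_t_only),
                      rep("cfDNA_only", n_private - n_t_only)))
      variants <- data.frame(chrom = genome$chrom, pos = pos, ref = ref,
                             alt = alt, class = cls, genotype = "het",
                             stringsAsFactors = FALSE)
    }
    structure(list(variants = variants, tumour_fraction = tumour_fraction,
                   weights = weights, seed = seed),
              class = "truth_set")
  })
}

#' cfDNA fragment-length mixture
#'
#' Three components: mono-nucleosome Normal(166, 15) truncated at >= 50 bp,
#' di-nucleosome Normal(332, 25) truncated at >= 50 bp, and long necrotic
#' fragments Uniform(2000, 10000).
#'
#' @param n Number of fragments.
#' @param weights Mixture weights, summing to 1.
#' @param seed Integer seed.
#' @return Integer vector of fragment lengths.
#' @export
generate_fragment_lengths <- function(n, weights = c(0.85, 0.10, 0.05), seed) {
  if (n <= 0L) stop("n must be positive")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  withr::with_seed(seed, {
    comp <- sample.int(3L, n, replace = TRUE, prob = weights)
    out <- integer(n)
    trunc_normal <- function(m, mean, sd, lower) {
      x <- round(rnorm(m, mean, sd))
      bad <- which(x < lower)
      while (length(bad)) {
        x[bad] <- round(rnorm(length(bad), mean, sd))
        bad <- bad[x[bad] < lower]
      }
      x
    }
    n1 <- sum(comp == 1L); n2 <- sum(comp == 2L); n3 <- sum(comp == 3L)
    if (n1) out[comp == 1L] <- trunc_normal(n1, 166, 15, 50L)
    if (n2) out[comp == 2L] <- trunc_normal(n2, 332, 25, 50L)
    if (n3) out[comp == 3L] <- round(runif(n3, 2000, 10000))
    as.integer(out)
  })
}

# substitute sequencing errors into read strings; multiple errors in one read
# are applied in successive vectorised rounds so `substr<-` never sees a
# duplicated target
add_read_errors <- function(reads, err_rate) {
  if (err_rate <= 0) return(reads)
  L <- nchar(reads)
  k <- rbinom(length(reads), L, err_rate)
  tot <- sum(k)
  if (tot == 0L) return(reads)
  ridx <- rep.int(which(k > 0L), k[k > 0L])
  pos <- ceiling(runif(tot) * L[ridx])
  pick <- ceiling(runif(tot) * 3)  # which of the 3 non-matching bases
  o <- order(ridx)
  ridx <- ridx[o]; pos <- pos[o]; pick <- pick[o]
  round <- sequence(rle(ridx)$lengths)
  alt_tab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (r in seq_len(max(round))) {
    sel <- round == r
    i <- ridx[sel]; p <- pos[sel]
    x <- reads[i]
    cur <- substr(x, p, p)
    substr(x, p, p) <- alt_tab[cbind(match(cur, rownames(alt_tab)), pick[sel])]
    reads[i] <- x
  }
  reads
}

# simulate one sample's paired-end reads.
# variants: df(pos, alt, p_carry) where p_carry may be per-variant; for cfDNA
# the carry probability additionally depends on per-fragment tumour origin.
simulate_sample_reads <- function(genome, variants, n_frag, frag_len,
                                  read_len, err_rate, prefix,
                                  origin = NULL) {
  G <- genome$length
  frag_len <- pmin(frag_len, G)
  s <- ceiling(runif(n_frag) * (G - frag_len + 1L))
  e <- s + frag_len - 1L
  rl1 <- pmin(read_len, frag_len)
  rl2 <- rl1
  w1 <- substring(genome$sequence, s, s + rl1 - 1L)
  w2 <- substring(genome$sequence, e - rl2 + 1L, e)

  if (nrow(variants)) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(s, e),
      IRanges::IRanges(variants$pos, variants$pos))
    fi <- S4Vectors::queryHits(ov)
    vi <- S4Vectors::subjectHits(ov)
    if (length(fi)) {
      p_carry <- variants$p_carry[vi]
      if (!is.null(origin)) {
        som <- variants$somatic[vi]
        p_carry <- ifelse(som & !origin[fi], 0, p_carry)
      }
      carry <- runif(length(fi)) < p_carry
      fi <- fi[carry]; vi <- vi[carry]
      if (length(fi)) {
        vpos <- variants$pos[vi]
        valt <- variants$alt[vi]
        in1 <- vpos >= s[fi] & vpos <= s[fi] + rl1[fi] - 1L
        if (any(in1)) {
          i <- fi[in1]; off <- vpos[in1] - s[i] + 1L
          x <- w1[i]; substr(x, off, off) <- valt[in1]; w1[i] <- x
        }
        w2s <- e[fi] - rl2[fi] + 1L
        in2 <- vpos >= w2s & vpos <= e[fi]
        if (any(in2)) {
          i <- fi[in2]; off <- vpos[in2] - w2s[in2] + 1L
          x <- w2[i]; substr(x, off, off) <- valt[in2]; w2[i] <- x
        }
      }
    }
  }

  r1 <- add_read_errors(w1, err_rate)
  r2 <- add_read_errors(revcomp(w2), err_rate)
  qname <- sprintf("%s_f%07d", prefix, seq_len(n_frag))
  idx <- rep(seq_len(n_frag), each = 2L)
  mate <- rep(c(1L, 2L), n_frag)
  seqs <- as.vector(rbind(r1, r2))
  data.frame(qname = qname[idx], mate = mate, seq = seqs,
             qual = strrep("D", nchar(seqs)),  # fixed Q35, wgsim-style
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate trio paired-end reads (germline, tumour, cfDNA)
#'
#' Germline reads carry germline variants at heterozygous dosage; tumour
#' reads additionally carry clonal somatic variants (VAF 0.5); cfDNA reads
#' are a mixture of tumour-derived fragments (at `truth$tumour_fraction`) and
#' normal-derived fragments, with fragment lengths drawn from the cfDNA
#' mixture of [generate_fragment_lengths()]. Substitution errors are uniform
#' at `err_rate`.
#'
#' @param genome A `genome_fixture`.
#' @param truth A `truth_set` from [implant_variants()].
#' @param depth Expected coverage (read bases per genome base).
#' @param read_len Read length (bp).
#' @param err_rate Per-base substitution error rate, in [0, 0.02].
#' @param seed Integer seed.
#' @return Named list `germline`, `tumour`, `cfdna`, each a read data.frame
#'   (`qname`, `mate`, `seq`, `qual`).
#' @export
generate_trio_reads <- function(genome, truth, depth = 30, read_len = 100L,
                                err_rate = 0.005, seed = 1L) {
  stopifnot(inherits(genome, "genome_fixture"), inherits(truth, "truth_set"))
  if (depth <= 0) stop("depth must be positive")
  if (err_rate < 0 || err_rate > 0.02) stop("err_rate must be in [0, 0.02]")
  G <- genome$length
  n_frag <- max(1L, as.integer(round(depth * G / (2 * read_len))))
  v <- truth$variants

  germ_vars <- v[v$class == "germline", , drop = FALSE]
  germ_vars$p_carry <- rep(0.5, nrow(germ_vars))
  germ_vars$somatic <- rep(FALSE, nrow(germ_vars))

  tum_vars <- v[v$class %in% c("germline", "shared", "tumour_only"), , drop = FALSE]
  tum_vars$p_carry <- rep(0.5, nrow(tum_vars))
  tum_vars$somatic <- rep(FALSE, nrow(tum_vars))

  cf_vars <- v[v$class %in% c("germline", "shared", "cfDNA_only"), , drop = FALSE]
  cf_vars$p_carry <- rep(0.5, nrow(cf_vars))
  cf_vars$somatic <- cf_vars$class != "germline"

  covaris_len <- function(n) pmax(150L, as.integer(round(rnorm(n, 350, 50))))

  germline <- withr::with_seed(derive_seed(seed, 1L), {
    simulate_sample_reads(genome, germ_vars, n_frag, covaris_len(n_frag),
                          read_len, err_rate, "germ")
  })
  tumour <- withr::with_seed(derive_seed(seed, 2L), {
    simulate_sample_reads(genome, tum_vars, n_frag, covaris_len(n_frag),
                          read_len, err_rate, "tum")
  })
  cf_len <- generate_fragment_lengths(n_frag, truth$weights,
                                      derive_seed(seed, 3L))
  cfdna <- withr::with_seed(derive_seed(seed, 4L), {
    origin <- runif(n_frag) < truth$tumour_fraction
    simulate_sample_reads(genome, cf_vars, n_frag, cf_len,
                          read_len, err_rate, "cf", origin = origin)
  })
  list(germline = germline, tumour = tumour, cfdna = cfdna)
}

#' Simulate fusion-junction-spanning reads
#'
#' Each emitted read is a window of its junction sequence that covers the
#' breakpoint with at least `min_overhang` bases on both sides; requested
#' per-junction counts are produced exactly.
#'
#' @param junction_db Junction table from [load_junction_db()] or
#'   [make_junction_db()].
#' @param support Named integer vector: junction id -> number of reads.
#' @param read_len Read length.
#' @param err_rate Uniform substitution error rate.
#' @param seed Integer seed.
#' @param min_overhang Minimum bases on each side of the breakpoint.
#' @return Read data.frame (`qname`, `mate` = NA, `seq`, `qual`).
#' @export
generate_fusion_reads <- function(junction_db, support, read_len = 100L,
                                  err_rate = 0, seed = 1L,
                                  min_overhang = 10L) {
  unknown <- setdiff(names(support), junction_db$id)
  if (length(unknown)) {
    stop("support requested for unknown junction: ",
         paste(unknown, collapse = ", "))
  }
  withr::with_seed(seed, {
    out <- list()
    for (jid in names(support)) {
      n <- support[[jid]]
      if (n <= 0L) next
      row <- junction_db[junction_db$id == jid, ]
      jlen <- nchar(row$sequence)
      if (jlen < read_len) stop("junction ", jid, " shorter than read length")
      b <- row$breakpoint
      lo <- max(1L, b + min_overhang - read_len + 1L)
      hi <- min(b - min_overhang + 1L, jlen - read_len + 1L)
      if (lo > hi) stop("junction ", jid, " cannot host a spanning read")
      s <- lo + floor(runif(n) * (hi - lo + 1L))
      seqs <- substring(row$sequence, s, s + read_len - 1L)
      flip <- runif(n) < 0.5
      seqs[flip] <- revcomp(seqs[flip])
      seqs <- add_read_errors(seqs, err_rate)
      out[[jid]] <- data.frame(
        qname = sprintf("fus_%s_%04d", gsub("[^A-Za-z0-9]", "", jid),
                        seq_len(n)),
        mate = NA_integer_, seq = seqs, qual = strrep("D", nchar(seqs)),
        row.names = NULL, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(qname = character(), mate = integer(), seq = character(),
                 qual = character(), stringsAsFactors = FALSE)
  })
}

#' Cohort configuration for plasma cfDNA concentrations
#'
#' Defaults are the study conditions: GBM patients 22.6 +/- 5 ng/mL, healthy
#' controls 1.4 +/- 0.4 ng/mL, 25 subjects per arm.
#'
#' @param n_gbm,n_control Group sizes.
#' @param gbm_mean,gbm_sd,control_mean,control_sd Group parameters (ng/mL).
#' @export
cohort_config <- function(n_gbm = 25L, n_control = 25L,
                          gbm_mean = 22.6, gbm_sd = 5,
                          control_mean = 1.4, control_sd = 0.4) {
  if (gbm_mean <= 0 || control_mean <= 0) stop("means must be positive")
  if (gbm_sd < 0 || control_sd < 0) stop("sds must be non-negative")
  if (n_gbm < 1L || n_control < 1L) stop("each group needs n >= 1")
  list(n_gbm = as.integer(n_gbm), n_control = as.integer(n_control),
       gbm_mean = gbm_mean, gbm_sd = gbm_sd,
       control_mean = control_mean, control_sd = control_sd)
}

#' Simulate cohort cfDNA concentrations
#'
#' Normal draws per group, truncated below at 0.01 ng/mL.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with numeric vectors `gbm` and `control` (ng/mL).
#' @export
generate_concentrations <- function(config = cohort_config(), seed = 1L) {
  withr::with_seed(seed, {
    list(gbm = pmax(0.01, rnorm(config$n_gbm, config$gbm_mean, config$gbm_sd)),
         control = pmax(0.01, rnorm(config$n_control, config$control_mean,
                                    config$control_sd)))
  })
}
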