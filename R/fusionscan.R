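# Chimera-junction fusion detection: align genome-unmapped reads to a
# database of junction sequences, count breakpoint-spanning fragments,
# call fusions with a decoy-competition FDR estimate, and annotate
# druggability from a curated fusion -> drug table.

#' Load a junction database from FASTA
#'
#' Headers must match `header_pattern`, capturing the junction id and the
#' 1-based breakpoint offset (position of the last base of the 5' partner).
#' Ids starting with `DECOY:` are marked as decoys.
#'
#' @param fasta Path to a FASTA file, or a data.frame from [read_fasta()].
#' @param header_pattern Regex with two capture groups (id, offset).
#' @return Data.frame: `id`, `sequence`, `breakpoint`, `source`.
#' @export
load_junction_db <- function(fasta, header_pattern = "^(.+)\\|bp=([0-9]+)$") {
  rec <- if (is.character(fasta)) read_fasta(fasta) else fasta
  m <- regmatches(rec$id, regexec(header_pattern, rec$id))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) {
    stop("junction header lacks a breakpoint offset: ", rec$id[bad[1L]])
  }
  id <- vapply(m, `[[`, character(1), 2L)
  bp <- as.integer(vapply(m, `[[`, character(1), 3L))
  if (anyDuplicated(id)) {
    stop("duplicate junction id: ", id[duplicated(id)][1L])
  }
  len <- nchar(rec$sequence)
  if (any(bp < 1L | bp >= len)) {
    stop("breakpoint offset outside sequence for ",
         id[which(bp < 1L | bp >= len)[1L]])
  }
  data.frame(id = id, sequence = rec$sequence, breakpoint = bp,
             source = ifelse(startsWith(id, "DECOY:"), "decoy", "target"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Junction FASTA records with breakpoint-carrying headers
#' @param db Junction data.frame.
#' @export
junction_fasta_records <- function(db) {
  data.frame(id = paste0(db$id, "|bp=", db$breakpoint),
             sequence = db$sequence, stringsAsFactors = FALSE)
}

#' Build a synthetic junction database
#'
#' Emulates a chimera-junction reference: each junction is a random 5' arm
#' joined to a random 3' arm at a known breakpoint. Junction ids are
#' `GENE5P-GENE3P` strings.
#'
#' @param pairs Character vector of junction ids (e.g. `"KDR-PDGFRA"`).
#' @param arm_len Arm length on each side of the breakpoint.
#' @param seed Integer seed.
#' @export
make_junction_db <- function(pairs, arm_len = 100L, seed = 1L) {
  withr::with_seed(seed, {
    seqs <- vapply(pairs, function(p) {
      paste(sample(BASES, 2L * arm_len, replace = TRUE), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    data.frame(id = pairs, sequence = seqs, breakpoint = arm_len,
               source = "target", row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Build shuffled-partner decoy junctions
#'
#' Re-pairs the 5' arms with a derangement of the 3' arms, skipping any
#' pairing present in the target set; decoy ids carry a `DECOY:` prefix.
#' The decoy set has the same size and length distribution as the targets.
#'
#' @param db Target junction data.frame.
#' @param seed Integer seed.
#' @export
make_decoy_junctions <- function(db, seed = 1L) {
  n <- nrow(db)
  if (n < 2L) stop("need at least two target junctions to build decoys")
  arms5 <- substring(db$sequence, 1L, db$breakpoint)
  arms3 <- substring(db$sequence, db$breakpoint + 1L)
  g5 <- sub("-.*$", "", db$id)
  g3 <- sub("^.*-", "", db$id)
  withr::with_seed(seed, {
    repeat {
      perm <- sample.int(n)
      new_id <- paste0(g5, "-", g3[perm])
      if (!any(perm == seq_len(n)) && !any(new_id %in% db$id)) break
    }
    data.frame(id = paste0("DECOY:", new_id),
               sequence = paste0(arms5, arms3[perm]),
               breakpoint = nchar(arms5), source = "decoy",
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Scan unmapped reads against a junction database
#'
#' A read supports a junction iff its best ungapped placement (either
#' orientation, exhaustive over offsets) has identity >= `min_identity` and
#' covers the breakpoint with at least `min_overhang` bases on both sides.
#' Each read counts towards its single best junction only (ties across
#' junctions discard the read, with a message); each fragment (read pair)
#' counts at most once per junction.
#'
#' @param reads Read data.frame (`qname`, `mate`, `seq`).
#' @param junctions Junction data.frame.
#' @param min_overhang Minimum bases each side of the breakpoint.
#' @param min_identity Minimum placement identity.
#' @return Named integer vector of per-junction supporting fragment counts
#'   (zero included), with the ambiguous-read count as attribute
#'   `dropped_ties`.
#' @export
scan_unmapped <- function(reads, junctions, min_overhang = 10L,
                          min_identity = 0.95) {
  if (any(nchar(junctions$sequence) < 2L * min_overhang)) {
    stop("junction sequences must be at least 2*min_overhang long")
  }
  support_frags <- setNames(vector("list", nrow(junctions)), junctions$id)
  dropped <- 0L
  for (i in seq_len(nrow(reads))) {
    rd <- reads$seq[i]
    L <- nchar(rd)
    rc <- revcomp(rd)
    best_mm <- Inf
    best_j <- NA_character_
    tie <- FALSE
    for (j in seq_len(nrow(junctions))) {
      S <- junctions$sequence[j]
      nS <- nchar(S)
      if (L > nS) next
      b <- junctions$breakpoint[j]
      lo <- max(1L, b + min_overhang - L + 1L)
      hi <- min(b - min_overhang + 1L, nS - L + 1L)
      if (lo > hi) next
      mm <- min(cpp_hamming_profile(S, rd)[lo:hi],
                cpp_hamming_profile(S, rc)[lo:hi])
      if (1 - mm / L < min_identity) next
      if (mm < best_mm) {
        best_mm <- mm
        best_j <- junctions$id[j]
        tie <- FALSE
      } else if (mm == best_mm) {
        tie <- TRUE
      }
    }
    if (is.finite(best_mm)) {
      if (tie) {
        dropped <- dropped + 1L
      } else {
        support_frags[[best_j]] <- c(support_frags[[best_j]], reads$qname[i])
      }
    }
  }
  if (dropped > 0L) message(dropped, " ambiguous read(s) dropped")
  out <- vapply(support_frags, function(x) length(unique(x)), integer(1))
  attr(out, "dropped_ties") <- dropped
  out
}

#' Call fusions from target and decoy support counts
#'
#' Candidates are target junctions with at least `min_support` supporting
#' fragments. The call-set FDR estimate is the number of decoy junctions
#' reaching `min_support`, divided by the number of candidates; all
#' candidates are emitted with `passed = (FDR <= max_fdr)`.
#'
#' @param support Named counts for target junctions ([scan_unmapped()]).
#' @param decoy_support Named counts for decoy junctions.
#' @param min_support Minimum breakpoint-spanning fragments.
#' @param max_fdr Maximum tolerated decoy FDR.
#' @return Data.frame: `junction`, `support`, `fdr`, `passed`, `note`.
#' @export
call_fusions <- function(support, decoy_support, min_support = 10L,
                         max_fdr = 0.05) {
  cand <- support[support >= min_support]
  no_decoys <- length(decoy_support) == 0L
  if (no_decoys) {
    fdr <- NA_real_
    passed <- rep(NA, length(cand))
  } else {
    d <- sum(decoy_support >= min_support)
    fdr <- d / max(1L, length(cand))
    passed <- rep(fdr <= max_fdr, length(cand))
  }
  data.frame(junction = names(cand), support = as.integer(cand),
             fdr = rep(fdr, length(cand)), passed = passed,
             note = rep(if (no_decoys) "fdr_undefined_no_decoys" else "",
                        length(cand)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a fusion -> drugs map
#'
#' @param path TSV with columns `fusion` and `drugs` (semicolon-joined).
#' @return Data.frame `fusion`, `drugs` (list column of character vectors).
#' @export
read_drug_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                  comment.char = "")
  if (any(!nzchar(d$drugs))) stop("drug map rows must list at least one drug")
  d$drugs <- strsplit(d$drugs, ";", fixed = TRUE)
  d
}

#' The packaged druggable-fusion map and its alias table
#'
#' Transcribed from the study cohort's observed-fusion table. The alias maps
#' the common alternative spelling `BCR-ABL1` to the tabulated `BCR-ABL`.
#' @export
default_drug_map <- function() {
  read_drug_map(system.file("extdata", "table4_drug_map.tsv",
                            package = "cftrio"))
}

#' @rdname default_drug_map
#' @export
fusion_id_aliases <- function() {
  c("BCR-ABL1" = "BCR-ABL")
}

#' Attach drug annotations to fusion calls
#'
#' Drugs are looked up by exact fusion id (order-sensitive: `BCR-ABL1` and
#' `ABL1-BCR` are different fusions), with a curated alias table for
#' spelling variants. Unknown fusions get an empty drug list and the flag
#' `no_known_drug`.
#'
#' @param calls Fusion calls ([call_fusions()]) or any data.frame with a
#'   `junction` column.
#' @param drug_map Data.frame from [read_drug_map()].
#' @param aliases Named character vector of id aliases.
#' @export
annotate_druggable <- function(calls, drug_map = default_drug_map(),
                               aliases = fusion_id_aliases()) {
  ids <- calls$junction
  canonical <- ifelse(ids %in% names(aliases), unname(aliases[ids]), ids)
  m <- match(canonical, drug_map$fusion)
  calls$drugs <- lapply(m, function(i) {
    if (is.na(i)) character(0) else drug_map$drugs[[i]]
  })
  calls$flag <- ifelse(is.na(m), "no_known_drug", "")
  calls
}

#' Cohort fusion frequencies
#'
#' Fraction of samples carrying each fusion; samples may carry several
#' fusions and fusion-free samples count in the denominator.
#'
#' @param sample_fusions Data.frame with columns `sample` and `fusion`
#'   (empty/NA fusion marks a fusion-free sample), or a named list of
#'   character vectors.
#' @return Data.frame `fusion`, `n_samples`, `frequency`, sorted by
#'   decreasing frequency then id.
#' @export
cohort_fusion_frequency <- function(sample_fusions) {
  if (is.list(sample_fusions) && !is.data.frame(sample_fusions)) {
    sample_fusions <- data.frame(
      sample = rep(names(sample_fusions), lengths(sample_fusions)),
      fusion = unlist(sample_fusions, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  n <- length(unique(sample_fusions$sample))
  if (n < 1L) stop("need at least one sample")
  has <- sample_fusions[!is.na(sample_fusions$fusion) &
                          nzchar(sample_fusions$fusion), , drop = FALSE]
  if (nrow(has) == 0L) {
    return(data.frame(fusion = character(), n_samples = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  counts <- tapply(has$sample, has$fusion, function(s) length(unique(s)))
  out <- data.frame(fusion = names(counts),
                    n_samples = as.integer(counts),
                    frequency = as.numeric(counts) / n,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$frequency, out$fusion), , drop = FALSE]
}

#' The packaged 25-sample cohort fusion table
#'
#' Observed druggable fusions per patient, transcribed from the study
#' cohort table (three samples carry no fusion call).
#' @export
table4_cohort <- function() {
  read.delim(system.file("extdata", "table4_cohort_fusions.tsv",
                         package = "cftrio"),
             stringsAsFactors = FALSE, quote = "", comment.char = "",
             na.strings = NULL)
}
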