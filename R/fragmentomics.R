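# Fragment-length profiling of cfDNA: window-based decomposition into
# apoptotic mono-/di-nucleosome fractions and a long necrotic fraction, plus
# the cohort plasma-concentration comparison.

#' Profile cfDNA fragment lengths
#'
#' Classifies fragment lengths into fixed windows: mono-nucleosome
#' `[100, 250)`, di-nucleosome `[250, 600)`, necrotic `>= 1000`. Lengths
#' outside every window are reported as unassigned. With
#' `tri_window = TRUE` a tri-nucleosome window `[450, 600)` is split out of
#' the di window.
#'
#' @param lengths Vector of positive fragment lengths (bp).
#' @param tri_window Report a separate tri-nucleosome window `[450, 600)`.
#' @return A `fragment_profile`: list with `histogram` (table), `n`, and
#'   `fractions` (named numeric, summing to <= 1 with the remainder
#'   unassigned).
#' @export
profile_lengths <- function(lengths, tri_window = FALSE) {
  if (length(lengths) == 0L) stop("no fragment lengths supplied")
  if (any(lengths <= 0)) stop("fragment lengths must be positive")
  n <- length(lengths)
  mono <- sum(lengths >= 100 & lengths < 250) / n
  di_hi <- if (tri_window) 450 else 600
  di <- sum(lengths >= 250 & lengths < di_hi) / n
  necrotic <- sum(lengths >= 1000) / n
  fr <- c(mono = mono, di = di)
  if (tri_window) fr <- c(fr, tri = sum(lengths >= 450 & lengths < 600) / n)
  fr <- c(fr, necrotic = necrotic)
  fr <- c(fr, unassigned = 1 - sum(fr))
  structure(list(histogram = table(lengths), n = n, fractions = fr),
            class = "fragment_profile")
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("fragment_profile: %d fragments\n", x$n))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Fragment lengths from paired SAM records
#'
#' One length per properly paired fragment: the outer distance between the
#' two mate placements. Records whose qname does not occur exactly twice are
#' skipped (a message reports how many).
#'
#' @param records SAM data.frame (see [read_sam()]).
#' @return Integer vector of fragment lengths.
#' @export
lengths_from_sam <- function(records) {
  if (nrow(records) == 0L) return(integer(0))
  records <- records[!records$unmapped, , drop = FALSE]
  tab <- table(records$qname)
  good <- names(tab)[tab == 2L]
  skipped <- sum(tab[tab != 2L])
  if (skipped > 0) message(skipped, " unpaired record(s) skipped")
  if (length(good) == 0L) return(integer(0))
  keep <- records$qname %in% good
  pos <- records$pos[keep]
  ends <- pos + nchar(records$seq[keep]) - 1L
  qn <- records$qname[keep]
  starts <- tapply(pos, qn, min)
  stops <- tapply(ends, qn, max)
  as.integer(stops - starts + 1L)
}

#' Compare cohort cfDNA concentrations
#'
#' Welch two-sample two-sided t-test (the group variances differ roughly
#' ten-fold between patients and controls, so a pooled test is not used).
#'
#' @param gbm,control Numeric concentration vectors (ng/mL), n >= 2 each.
#' @return List: `t`, `p`, `means`, `sds`, `df`.
#' @export
compare_concentrations <- function(gbm, control) {
  if (length(gbm) < 2L || length(control) < 2L) stop("each group needs n >= 2")
  means <- c(gbm = mean(gbm), control = mean(control))
  sds <- c(gbm = stats::sd(gbm), control = stats::sd(control))
  if (sds[1L] == 0 && sds[2L] == 0) {
    if (means[1L] == means[2L]) {
      return(list(t = 0, p = 1, means = means, sds = sds, df = NA_real_))
    }
    return(list(t = sign(means[1L] - means[2L]) * Inf, p = 0,
                means = means, sds = sds, df = NA_real_))
  }
  ht <- t.test(gbm, control, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, means = means, sds = sds,
       df = unname(ht$parameter))
}
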