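---
title: "Methods: trio liquid-biopsy analysis of plasma cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio liquid-biopsy analysis of plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Glioblastoma sheds fragmented DNA into plasma. This circulating cell-free
DNA (cfDNA) carries two exploitable signals: its *physical* structure
(apoptotic fragments trimmed around nucleosomes at about 166 bp and 332 bp,
against a long tail of necrotic fragments above 1000 bp, at roughly
85/10/5 proportions and sharply elevated total concentration in patients),
and its *genetic* content (somatic point mutations and gene-gene fusions
shared with the tumour). `cftrio` implements the full desk-scale analysis:
fragment-size decomposition, trio somatic SNV calling with germline
subtraction, consequence annotation, chimera-junction fusion detection with
druggable-fusion annotation, and a two-gene-set pathway comparison —
together with a deterministic synthetic-data generator so every stage can
be scored against known truth.

Real patient data for this design are not publicly deposited, so the
package's empirical claims are all statements about synthetic data whose
generating parameters are the study conditions: 30x paired-end 100 bp
trios, a 166/332/long fragment mixture at 85/10/5, cohort concentrations
of 22.6 +/- 5 ng/mL (patients) versus 1.4 +/- 0.4 ng/mL (controls), a
10-read fusion support floor at 5% FDR, and 80%/90%
sensitivity/"selectivity" floors for shared somatic recovery.

## Fragmentomics

`profile_lengths()` classifies fragment lengths into fixed windows:
mono-nucleosome [100, 250), di-nucleosome [250, 600), necrotic >= 1000 bp,
with anything else reported as unassigned. We deliberately use transparent
window counting rather than fitting a Gaussian mixture by EM: the
quantities of interest are peak *fractions*, the windows sit midway between
the stated peak centres, and window counts are exactly testable against a
counting oracle. A tri-nucleosome window [450, 600) can be split out with
`tri_window = TRUE`; it is off by default because the long-fragment
component of the default mixture starts at 2000 bp, leaving [600, 1000)
empty. Fractions are computed per sample; callers who want cohort-pooled
fractions can concatenate length vectors before profiling.

`compare_concentrations()` is a Welch two-sample two-sided t-test. The
patient and control variances differ by more than an order of magnitude
(5^2 vs 0.4^2 (ng/mL)^2), which makes a pooled-variance test indefensible;
Welch is the conservative default. Degenerate inputs (both groups
constant) return t = 0, p = 1 when equal and p = 0 otherwise.

The generator draws mono and di lengths from Normal(166, 15) and
Normal(332, 25) truncated at 50 bp, and necrotic lengths from
Uniform(2000, 10000). Only the peak centres and weights are given by the
study; the standard deviations (15, 25) are our choice, set so the
components are cleanly separable by the window classifier while still
overlapping realistically in the 240-260 bp region.

## Read simulation and mapping

`generate_trio_reads()` emits paired 100 bp reads at 30x expected coverage
for three samples. Germline heterozygous SNPs appear at dosage 0.5
everywhere; clonal somatic variants appear at dosage 0.5 in the tumour; the
cfDNA sample is a per-fragment mixture in which a fraction
`tumour_fraction` (default 0.4) of fragments is tumour-derived and can
carry somatic alleles. Subclonality, indels and copy-number changes are out
of scope, so passing tests say nothing about those failure modes on real
data. Variant spacing is forced to >= 150 bp so that a 100 bp read window
never carries two variants, which keeps the caller's unit of evaluation a
single site. Written base qualities are fixed at Q35 while the substitution
error rate is an independent parameter (0.5% by default) — the same
simplification classic read simulators make — so the genotype model runs
slightly optimistic about error rates; the end-to-end recovery results
below absorb that miscalibration.

The internal mapper is a seed-and-extend, ungapped, end-to-end aligner
over a 2-bit k-mer index (default k = 15, seeds every floor(k/2) bases on
both orientations). Ungapped alignment is sufficient because the simulator
produces substitutions only. A read is unmapped when no seeded placement
reaches a mismatch rate of 5% of its length — the same identity floor the
fusion scanner uses. MAPQ is 60 for a unique best placement, 0 on ties
(lowest coordinate reported), and otherwise scales with the gap between
the best and second-best placements. These choices are deliberately simple
and monotone; the mapper's contract is verified against a brute-force
all-placements oracle in the test suite, not against a production aligner.

## Trio somatic calling

Calling follows the classical seven-stage pileup path. For each sample:

1. pileup columns are built from the ungapped alignments (indels cannot
   arise);
2. at each column the biallelic diploid genotype likelihood is evaluated:
   for alt dosage g in {0, 1, 2} an observed base b contributes
   `(1 - g/2) P(b|ref) + (g/2) P(b|alt)`, with `P(b|a) = 1 - e` when
   `b == a` and `e/3` otherwise, `e = 10^(-Q/10)`; the alt allele is the
   most frequent non-reference base (multiallelic sites collapse to it);
   a call is emitted when the maximum-likelihood dosage is >= 1, with
   QUAL the phred-scaled posterior odds against dosage 0 under a uniform
   prior;
3. normalisation is an explicit identity (left-alignment only moves
   indels) kept so the stage structure and its logging survive;
4. varFilter-style rules remove calls with depth outside [2, 1e7], fewer
   than 2 alternate reads, RMS mapping quality below 10, or any PV4 bias
   p-value below its floor (strand 1e-4, baseQ 1e-100, mapQ 0,
   end-distance 1e-4), labelling each removal with the first failing rule;
5. germline records are subtracted from tumour and cfDNA calls by the
   full (chrom, pos, ref, alt) key — record-level matching, not
   position-level, mirroring how VCF set operations behave;
6. the tumour and cfDNA somatic sets are intersected on the same key,
   retaining tumour-side annotations and recording cfDNA depth alongside.

PV4 is computed as a two-sided Fisher exact test for strand bias and
two-sided Mann-Whitney tests (normal approximation with tie correction)
for base-quality, mapping-quality and end-distance bias; these are
standard, fully specifiable equivalents of the undocumented internal
tests of the classical tools. The HWE rule is a pass-through for
single-sample calls — it needs cross-sample genotype counts that a
single-sample VCF does not have — and the gap-adjacency rules are inert
without indels; both are retained as explicit no-ops for fidelity.

Two quantities needed interpretation. "Selectivity" is reported as
*precision* (true shared calls / all shared calls); both precision and the
full confusion counts are returned so a specificity-style reading can be
recomputed. The 5% FDR attached to mutation sharing has no published
procedure; we operationalise it as a QUAL floor (default 20) applied to
both sides of the shared set, which on synthetic data holds the expected
false-discovery proportion of shared calls far below 5% because false
calls in tumour and cfDNA arise at independent sites. For genome-scale
runs the compiled pileup only materialises observations at sites with at
least two reads of one non-reference base — an mpileup-style candidate
screen that is lossless with respect to the downstream two-alternate-reads
rule (single-alt-read calls would be filtered anyway, as the unit API
demonstrates).

## Consequence annotation

`classify_variant()` maps each SNV to exactly one most-severe term from a
closed 15-term vocabulary (splice donor/acceptor, stop gained, missense,
splice region, synonymous, 5'/3' UTR, non-coding exon, intron,
up/downstream, TF binding site, regulatory region, intergenic), with the
fixed impact table HIGH/MODERATE/LOW/MODIFIER. Splice donor/acceptor are
the first/last two intronic bases; the splice region covers exonic bases
1-3 and intronic bases 3-8 from an internal junction; coding terms come
from codon translation on the gene's strand; up/downstream extend 5 kb
from the transcript (the common annotator default, exposed as `flank`).
One transcript per gene is assumed — the fixture generator produces one —
and terms outside the vocabulary (start/stop-loss) fold into missense so
the output vocabulary stays closed. Both the full per-term distribution
and the HIGH-impact subset are reported, since published summaries of this
shape mix the two readings.

## Fusion detection

Genome-unmapped reads are scanned against a junction database (each record
a 5' arm joined to a 3' arm with a declared breakpoint offset, id format
`GENE5P-GENE3P|bp=<offset>` — the header dialect is a configurable regex
since chimera databases vary). A read supports a junction when its best
ungapped placement reaches 95% identity *and* covers the breakpoint with
at least 10 bases on each side; the overhang and identity guards are the
scanner's protection against one-sided, non-chimeric matches. Junction
sequences are short, so the scanner evaluates every placement exhaustively
rather than seeding — which is also why it takes no k-mer size parameter.
Each read is credited to its single best junction (ties discard the read)
and each fragment counts once per junction.

Calls require at least 10 supporting fragments. FDR is estimated by
target-decoy competition: decoys are shuffled re-pairings of the real 5'
and 3' arms (derangement, excluding any real pairing), matched in number
and length; the estimate is decoys-over-threshold divided by candidate
count, and calls pass when it is at most 5%. Drug annotation is an exact,
order-sensitive id lookup in the packaged fusion-to-drug table (with a
curated alias for the BCR-ABL/BCR-ABL1 spelling pair); cohort frequency is
the fraction of samples carrying a fusion, fusion-free samples included in
the denominator.

## Pathway over-representation

The published analysis feeds two unranked gene lists to a web
over-representation service; accordingly `ora()` implements the
hypergeometric upper-tail test (not rank-based enrichment), with
Benjamini-Hochberg adjustment and a deterministic rank (p-value, then
pathway id). The universe defaults to the union of all pathway genes and
the query set, the least surprising choice when the reference is
unspecified. The comparison of two analyses follows the published top-100
rule via `common_pathways()`; a q <= 0.05 mode is available by filtering
on the q column. The real pathway reference is not shipped (licensing and
version drift); `make_pathway_db()` builds a synthetic database of 206
pathways in which six named cancer-signalling pathways contain genes from
both the frequently-mutated and the frequently-fused panels, and 100
pathways per side overlap only one panel — so the two top-100 rankings
share exactly those six, giving the intersection logic a fully determined
fixture. The six real pathway names label that fixture; nothing about real
pathway membership is claimed.

## Determinism and problem sizes

Every generator runs under `withr::with_seed()` on a single integer seed;
stage seeds are derived by fixed offsets, and all outputs are
byte-deterministic (the test suite checksums demo runs). The package's own
evaluations use a 500 kb genome with 20 genes, 300 germline + 60 shared
somatic SNVs, 30x PE-100 trios at 0.5% error and tumour fraction 0.4 for
somatic recovery; 100 000 fragments for the mixture decomposition; and
10/9/3-read junction implants against 20-junction target and decoy sets
for the fusion thresholds. These sizes keep a full end-to-end run in the
tens of seconds on one core while leaving every per-site statistic at its
study-scale operating point (depth, VAF, error rate).

## Known limitations

* Uniform substitution errors, fixed written quality, no indels, no CNVs,
  no subclonality: recovery figures on synthetic data are upper bounds on
  real-data behaviour.
* The mapper and scanner are ungapped by design; junction reads with
  indels near the breakpoint would lose support.
* Single-transcript gene models; per-transcript multi-annotation is
  collapsed to the most severe term.
* The concentration generator uses truncated normals although the
  reported patient range (12.6-137 ng/mL) suggests right skew; the t-test
  conclusion is insensitive to this at the stated effect size.
* `run_demo()` and the R functions are the interface; there is no shell
  subcommand wrapper.
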