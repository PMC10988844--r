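---
title: "Repeat-element enrichment analysis with renrich: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-element enrichment analysis with renrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Repeat elements (REs) — LINEs, SINEs, LTR retrotransposons, SVAs,
satellites and simple repeats — make up a large fraction of mammalian
genomes, and chromatin pulldown experiments (ChIP-seq, CIDOP-seq) often
enrich or deplete them as a class. Quantifying this is awkward with
standard peak-centric workflows: RE-derived reads are multimapping, so
per-locus signals are unreliable, and the interesting quantity is the
*aggregate* representation of each RE subfamily across all of its genomic
copies. `renrich` implements a genome-wide, coordinate-aggregated analysis:
reads are counted onto all instances of each named RE subfamily, summed per
name, normalised, and compared between pulldown and input chromatin.

## The analysis model

For each library the count $c_i$ of reads on RE name $i$ is turned into a
density

$$d_i = \frac{\max(c_i,\; 0.1)}{N},$$

where $N$ is the library size (the number of primary mapped reads) and 0.1
is a pseudocount that keeps densities positive and ratios finite.
Normalising to $N$ converts counts to probabilities within the library, so
libraries of different depth are comparable. The enrichment of name $i$ in
one replicate pair is the ratio of pulldown to input densities,
$e_i = d_i^{\mathrm{chip}} / d_i^{\mathrm{input}}$; the input library is
the baseline of RE representation in the starting chromatin and cancels
composition, amplification and mappability effects common to both.

With two biological replicate pairs the reproducibility statistic per name
is

$$Z_i = \frac{\left|\bar e_i - 1\right|}{\sigma_i},\qquad
  p_i = P\!\left(\mathcal N(0,1) > Z_i\right),$$

with $\bar e_i$ the arithmetic mean and $\sigma_i$ the *population*
standard deviation ($n = 2$ in the divisor) of the two ratios. For the
volcano plot the p-values are floored at $10^{-16}$, ranked ascending and
adjusted to $p_{(k)} \cdot N_{\mathrm{RE}} / k$, capped at 1. This is the
plain rank formula applied verbatim; the classical monotone (step-up)
Benjamini–Hochberg variant is available as `fdr_adjust(method = "bh")` but
is deliberately not the default, because the rank formula is what the
analysis defines. Family-level summaries divide the summed member densities
by the number of member subfamilies before forming ratios, so large and
small families are on the same scale.

### Calibration of the two-replicate statistic

A property worth understanding before interpreting p-values: with only two
replicates, $Z$ is the ratio of a (folded, shifted) normal to an
independent half-normal, i.e. Cauchy-tailed under the null. Its null
distribution is therefore *not* standard normal, and
$P(p \le 0.05) \approx 0.35$ even for a perfectly null RE. The test suite
checks our implementation against an independent Monte-Carlo transcription
of the same formula rather than against nominal uniformity, and the
package's own simulations show that an unenriched family reaches
family-level FDR significance in roughly a fifth of runs. Two consequences
for users: (i) p-values order candidates well but should not be read as
calibrated error rates; (ii) an additional, real effect pushes non-target
families slightly below 1 whenever some family is strongly enriched,
because library renormalisation is zero-sum. Both effects are intrinsic to
the two-replicate design, not implementation artifacts.

## Counting semantics

Counting deliberately reproduces the overlap-tolerant, meta-feature
behaviour of `featureCounts -s 0 -Q 0 --primary -t exon -g gene_id -O -M
--minOverlap 1`:

* only primary alignments are used (SAM flags 256 and 2048 excluded), so a
  multimapping read is counted exactly once, at the location the aligner
  designated primary;
* MAPQ is never filtered — aligners zero the MAPQ of multimappers, and on
  repeats that would discard the signal of interest;
* a read is assigned to every distinct RE *name* it overlaps by at least
  one base; overlapping two instances (or two merged exons) of the same
  name counts once;
* mates of a pair are counted independently — the counting unit is the
  read, not the fragment. This matters: fragment-level counting would
  change every downstream number, and is documented here for that reason;
* the overlap is computed on the CIGAR reference span, so indels and
  clipping are handled the way the aligner saw them;
* reads on contigs absent from the annotation still count toward the
  library size, matching the flagstat definition of sequencing depth.

The interval engine is `GenomicRanges::findOverlaps`; an exhaustive
quadratic scan implemented independently in the test helpers must agree
exactly on randomised inputs before any release.

## Annotation adjustment

RepeatMasker BED12 rows describe a model span with block structure. The
adjustment extracts the blocks as exon intervals, then sorts and merges
overlapping intervals *of identical name*, applied twice. Intervals of
different names are never merged, and book-ended intervals (zero gap) are
kept separate — merging is strict-overlap union, the second pass is
verified idempotent, and per-name base coverage is conserved. In-memory
intervals are `GRanges` (1-based, closed), the native Bioconductor
convention; coordinates are converted only at the BED boundary (0-based,
half-open) and GTF output (1-based, closed) needs no shift. A single
internal convention at the container level is the whole point — the R
ecosystem supplies it, so we use it rather than carrying a parallel
0-based representation.

Grouping (name → family → class) is read from `name#family/class` BED
name fields or a sidecar TSV; the sidecar wins on conflict, and a name
with two assignments is an error naming the offender.

## The synthetic-data generator

`build_toy_genome()` plants multi-copy repeat subfamilies into random
background sequence. Defaults (see `default_repeat_catalog()`): a 1 Mb
genome (2 × 500 kb), eight subfamilies in five families (Alu, L1, SVA,
ERV1, Simple_repeat) with human-like lengths and copy numbers, occupying
≈11% of the genome; per-copy substitution divergence of 2–10% from the
subfamily consensus; random strand; non-overlapping placement. Every
placement is recorded as a single-block BED12 row, so the truth annotation
is exact.

`simulate_reads()` emulates a HiSeqX-like paired-end run: 150 bp reads,
fragment lengths Normal(450, 30) truncated below at the read length,
uniform fragment starts, uniform substitution errors with a flat Phred
quality consistent with the chosen rate. Indels are off by default so that
every read has an exact truth interval; that choice trades a little realism
for exact closure tests. `simulate_pulldown()` draws input fragments
uniformly and chip fragments by rejection sampling with weight equal to
the enrichment factor of any overlapped family — exactly the renormalised
start distribution, so the expected measured family ratio is
$E / (1 + (E-1)q)$ for planted factor $E$ on a family covering fragment
fraction $q$. Keeping planted families small ($q \lesssim 1\%$) makes the
renormalisation bias negligible relative to sampling noise.

What the generator does *not* emulate: GC and PCR amplification bias,
empirical quality profiles, indel errors, chimeric fragments, fragmented
or nested repeat copies, and — most importantly — the aligner itself. The
package consumes alignments; simulated "analysis" inputs are ground-truth
SAM files. Passing tests therefore validate annotation handling, counting,
normalisation, statistics and plumbing, not mapping quality on real
repeats.

## Numerical and design choices

* **Pseudocount 0.1** applied per RE before library normalisation, at the
  RE level also for family sums (pseudocount first, then sum) — the
  alternative order is not meaningfully different at realistic depths but
  one had to be fixed.
* **σ = 0 rows**: two identical ratios make $Z$ undefined. With
  $\bar e = 1$ the row reports $z = 0, p = 0.5$; otherwise
  $z = \infty, p = 0$. Both carry a `degenerate_sd` flag so the ambiguity
  stays visible instead of disappearing into the ranking.
* **FDR floor $10^{-16}$** is applied before ranking; ties in p are broken
  by name so ranks — and therefore output files — are byte-reproducible.
* **Volcano conventions**: position uses the raw p, colour uses the
  FDR-adjusted p; points with $|\log_2 \bar e| \le 0.5$ are greyed as not
  meaningful regardless of significance.
* **Bar-diagram exclusions**: Simple_repeat, Low_complexity, Unknown and
  tRNA are omitted by default — short, low-coverage categories whose
  enrichment estimates are unstable; the set is configurable.
* **Insert-size QC** measures each template once (positive-TLEN mate);
  an insert is an outlier when $|TLEN| \ge 2 \times$ the maximum reliable
  fragment size, boundary inclusive.
* **Full-length filter**: a region is full-length when some model span
  overlaps it reciprocally at ≥ 90% of both lengths; each region reports
  at most once. Requiring 100% rejects instances one base short and is
  documented as a false-negative mode.
* **Coverage tracks**: RPKM per fixed bin (default 10 bp), primary
  alignments only; anchored matrices use 50 bp bins, strand-aware
  flipping, zero fill beyond chromosome ends, and a mean-intensity row
  sort with a name tie-break for determinism.
* **Seeds are mandatory** for every simulation entry point; nothing seeds
  from the clock.

## Problem sizes used in the checks

The packaged checks run on the 1 Mb default genome: closure tests at
coverage 1 (≈3,300 pairs), enrichment-recovery runs at 100,000 pairs per
library (200k reads, mirroring a reduced-size demonstration dataset), the
null-calibration loop across 20 seeds via the truth-assignment path, and
randomized oracle comparisons with up to 10⁴ reads × 100 intervals. These
sizes were chosen so the full suite exercises every code path at depths
where binomial sampling error is a few percent.

## A worked run

```{r demo, eval = FALSE}
library(renrich)
res <- demo_run(seed = 1)   # builds fixtures, runs the pipeline,
                            # validates against ground truth
res$planted_family[, c("family", "mean", "sd", "p", "p_fdr")]
```

The demonstration plants a 4× enrichment on the ERV1 family, analyses the
four simulated libraries end to end, and checks closure (truth vs analysed
densities identical), correlation, and recovery of the planted factor.

## Limitations

* The statistic is defined for exactly two replicate pairs; more
  replicates would require a different (and better-calibrated) test.
* No aligner is bundled or invoked: the package starts at SAM/BAM.
  Upstream, a DNA-seq aligner run with spliced alignment disabled and an
  explicit maximum fragment length is assumed.
* p-values from the two-replicate Z are anticonservative (see above);
  treat them as a ranking device with a reproducibility flavour.
* The simulator's error model is uniform substitution; it is sufficient
  for validating the counting and statistics, not for benchmarking
  aligners.
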