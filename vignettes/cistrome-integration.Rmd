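---
title: "Cistrome-transcriptome integration: methods and design"
author: "cistromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cistrome-transcriptome integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromics)
```

# The analytical problem

When two transcription factors occupy overlapping regulatory landscapes —
here an androgen-receptor-like factor "A" whose binding is
treatment-stable and a MYC-like factor "B" whose binding collapses under
treatment — several distinct questions have to be answered from the same
few data types (peak calls, signal tracks, a TSS annotation, expression
tables):

1. How much of each cistrome is shared? (peak-set partition)
2. Which peaks are lost, retained or gained under treatment? (dynamics)
3. Which genes sit near which factor, and does that predict their
   expression response? (occupancy classes, regulatory potential,
   resampling enrichment)
4. Where are the super-enhancers and how does their signal shift?
5. How does a binding-derived gene signature behave across samples?

`cistromics` implements each step as a small, testable function over
`GRanges` peak sets, run-length-encoded signal tracks and plain gene
tables, plus a generator of fully synthetic datasets with planted ground
truth and a pipeline driver that chains all stages.

# Conventions

All files use BED conventions: 0-based, half-open intervals. In memory,
peak sets are `GRanges` (1-based, closed); the conversion happens only in
`read_bed` / `write_bed` and the bedGraph equivalents. Overlap anywhere in
the package means *at least one shared base*, strand-blind, and a peak
overlapping several partners is counted once (peak-anchored counting).
A TSS window of half-width $w$ is the half-open interval
$[\mathrm{tss} - w, \mathrm{tss} + w)$: a peak starting exactly at
$\mathrm{tss} + w$ is outside.

A signal track is piecewise-constant per base; bases not covered by any
bedGraph run read as zero. Chromosome lengths bound the track: a profile
window that crosses a chromosome end is *truncated* (averaged over the
covered bases only and flagged, and `mean_profile` excludes such rows),
whereas a window inside the chromosome but beyond the last run simply
reads zeros.

# Models and procedures

## Occupancy classes and class-wise contrasts

A gene is `common` when both factors have ≥1 peak in its ±`window_kb`
TSS window (default 10 kb, the conventional promoter-proximal annotation
distance), `A_only` / `B_only` when exactly one does, `none` otherwise.
The four classes partition the gene universe by construction. Class-wise
log2 fold-change distributions are compared pairwise with two-sided
Wilcoxon rank-sum tests and Benjamini–Hochberg adjustment across pairs.

## Resampling enrichment

For a query gene set, `resample_enrichment` computes the percentage of
genes with ≥1 peak within ±`window_kb` (default 20 kb for this analysis)
and draws `n_iter` random gene sets of the same size from the universe.
Three design choices matter:

* **Binary occupancy.** "Percentage of genes with peaks in proximity"
  counts a gene once regardless of how many peaks fall in its window;
  peak multiplicity is deliberately ignored.
* **Sampling without replacement.** Null draws are gene *sets* from the
  transcriptome, so each draw is a without-replacement sample.
* **Two p-values.** The one-sided one-sample t-test of the null
  percentages against the observed value is reported because it is the
  conventional summary, but a t-test on a bounded percentage is
  approximate, so the +1-corrected empirical p-value
  $(1 + \#\{null \ge obs\}) / (n_{iter} + 1)$ is the primary statistic.

The odds ratio is observed% / mean(null%). Degenerate cases are explicit:
an all-zero null with a positive observation reports `Inf` with a
warning; a fully unbound universe reports 0 with a warning.

## Regulatory potential and binding association

Each gene's regulatory potential is

$$ rp = \sum_{|c_i - t| \le L} e^{-(a + b \Delta_i)}, \qquad
   \Delta_i = |c_i - t| / L $$

over peak midpoints $c_i$ within $L$ of the TSS $t$, with the classical
decay constants $a = 0.5$, $b = 4$ and $L = 100$ kb — all three exposed as
parameters. A peak at the TSS contributes $e^{-0.5} \approx 0.607$, a peak
at the window edge $e^{-4.5} \approx 0.011$. The peak position is the
interval midpoint because summit information is not part of the BED
contract. The score is additive over peak sets and monotone nonincreasing
in every peak's distance.

`beta_association` ranks all genes by decreasing rp (ties broken by
gene id, for determinism), draws the cumulative-fraction curve of each
gene class along the ranking, and compares up- and down-regulated classes
against the static background with a one-sided two-sample
Kolmogorov–Smirnov test on rank positions (alternative: the regulated
class occupies better ranks). Only this binding-association half of the
classical target-analysis method is implemented; the product-of-ranks
target ranking and its permutation test are intentionally out of scope.

## Super-enhancers

Enhancer peaks are stitched transitively when gaps are ≤ 12.5 kb (the
conventional stitching distance); optional removal of peaks fully within
±2.5 kb of a TSS is available but **off by default**. Stitched regions
are ranked by total signal and placed on the unit square
($x$ = rank/$n$, $y$ = signal/max). The cutoff is the point where the
scaled curve's tangent has slope 1. For the convex "hockey-stick" curves
this method targets, the slope-1 tangent point is the *minimum* of
$y - x$ (the curve rises slower than the diagonal before the elbow and
faster after), so the cutoff is `argmin(y − x)` and super-enhancers are
the regions with signal strictly above the cutoff signal. This reproduces
the defining behaviours: in a `[1, 1, 1, 1, 100]` fixture exactly the
dominant region is flagged; with all-equal signals the curve offers no
elbow and zero super-enhancers are called (with a warning); the flag set
is invariant to uniform rescaling of the track. No input-track
subtraction is applied.

Per-region condition fold changes are
$\log_2((s_b + \epsilon) / (s_a + \epsilon))$ with signals summed over
the region in each track and pseudocount $\epsilon > 0$ (default 1).

## Pileups

`profile_matrix` tiles $[\mathrm{center} - f, \mathrm{center} + f)$ with
`bin_width` bins left to right (defaults $f = 2$ kb, 50 bp bins, hence 80
columns); the bin value is the mean track value over the bin's bases, and
the peak center is $\lfloor (start + end)/2 \rfloor$ in 0-based
coordinates. Terminal bins truncated by a chromosome end average over the
covered bases only.

## Signature z-scores

Per gene, $z = (x - \mu)/\sigma$ across samples; a sample's score is the
sum over signature genes present. $\sigma$ is the sample ($n-1$) standard
deviation — the natural reading of "study standard deviation" for a
finite cohort. Genes with zero variance are dropped with a warning, and
signature genes absent from the matrix are skipped and never imputed.
Because each gene's z-scores sum to zero, the per-sample scores sum to
zero across samples — a useful built-in identity check.

## Hypergeometric overlap

`hypergeom_overlap(k, K, n, N)` returns $P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$ via the standard stable upper-tail
routine. The universe $N$ — in practice the number of genes passing the
caller's expression filter — must be passed explicitly; the package never
infers it.

# The synthetic-data generator

The generator defines the study conditions once and is not meant to be
tuned per analysis. Defaults: 4 chromosomes × 30 Mb, 1000 genes, 2400
peaks per factor, co-binding fraction $\rho = 0.25$, loss fraction 0.59
and gain fraction 0.14 (the observed regime where roughly 15 thousand
B-factor peaks fall to ~8 thousand with ~2 thousand new ones), treated
intensity scale $\delta = 0.5$, signal background 0.1 against bump
amplitudes $\sim N(10, 2)$, planted expression effects of +1 (A-bound)
and −1 (B-only) log2 units with noise SD 0.2, six samples and a 136-gene
signature.

Key construction choices:

* **Exact ground truth by geometry.** All peaks are placed mutually
  non-overlapping *except* the planted common pairs: exactly
  $\mathrm{round}(\rho \cdot n_B)$ B peaks are contained within distinct
  A partners. Consequently the realized co-binding fraction, the overlap
  partition and the dynamics partition are exact counts, not statistical
  targets. Placement uses rejection sampling with a bounded budget and
  fails with advice to enlarge chromosomes rather than silently relaxing
  the constraints.
* **Unambiguous occupancy.** TSSs are placed uniformly per chromosome
  with a minimum spacing of twice the annotation-window span (40 kb for
  the 10 kb window), and peak centers stay `edge_margin` (5 kb) away from
  chromosome ends so profile windows never truncate — truncation handling
  is still implemented and tested on hand-built tracks.
* **Signal model.** Track value at base $x$ is
  $bg + \sum_i a_i \exp(-(x - c_i)^2 / (2 (w_i/4)^2))$: the bump SD of
  width/4 puts ~95% of the signal mass inside the peak interval. Values
  are evaluated on a 10 bp grid (at run starts) — a compromise between
  file size and pileup fidelity recorded in the manifest — and rounded to
  6 significant digits so that text round-trips are bit-exact.
* **Expression coupling.** The planted per-gene effect is constant within
  a class ($+$`expr_effect_a` for A-bound, $-$`expr_effect_b` for B-only,
  0 otherwise), which makes class means analytically checkable
  ($\pm \sigma_e/\sqrt{n}$). Because the planted B effect is constant,
  "the B-only genes with the largest planted effect" is a tie, resolved
  deterministically by gene id when selecting the signature.
* **Named RNG substreams.** Every stochastic stage draws from its own
  substream derived from the master seed, so adding a stage never
  perturbs earlier draws, and a manifest with per-file MD5 digests makes
  replay verifiable. BED scores are written as intensity × 1000 rounded
  (the BED integer-score convention), so peak intensities round-trip to
  within 0.0005.
* **The A cistrome is treatment-stable** in the simulation; only factor
  B has loss/gain/intensity dynamics. Effect sizes linking binding class
  to expression are free parameters of the generator, not estimates of
  any real system.

What the generator does *not* emulate: read-level noise (no FASTQ,
fragment-length or GC models), diploid genomes, copy-number variation,
correlated biological replicates, or peak-width/intensity dependence on
chromatin context. Passing tests on synthetic data therefore demonstrate
algorithmic correctness against planted truth, not robustness to every
artefact of real ChIP-seq.

# Numerical choices and degenerate inputs

* Ranking ties (regulatory potential, super-enhancer signal) are broken
  by identifier or coordinate, never by input order, so results are
  invariant to permutations of the input.
* `rank_enhancers` with all-equal signals warns and calls zero
  super-enhancers; `se_fold_change` treats regions outside the track
  extent as zero-signal with a warning; empty query classes in
  `beta_association` are skipped with a warning rather than failing the
  other class.
* The pipeline validates every input path before any computation and
  aborts naming the failing stage; reruns with identical config and seed
  produce byte-identical summaries (no timestamps enter any output).
* Problem sizes used by the test suite: brute-force oracles run at up to
  1000 genes × 5000 peaks (regulatory potential, exact equality), 1000
  random stitching fixtures of ≤300 peaks, 100-peak per-base profile
  oracles at 1e−9, 2000-replicate null calibration of the empirical p at
  `n_iter` = 1000, and one full default-size synthetic dataset through
  the pipeline. These sizes were chosen to exercise every code path at
  desk scale while keeping the suite quick to run.

# Known limitations

* Interval overlap is binary (≥1 bp); there is no reciprocal-overlap
  fraction option.
* The regulatory-potential decay treats all peaks equally; no
  intensity weighting is applied (the classical formulation).
* The one-sided KS p-value is asymptotic; for very small classes an exact
  permutation approach would be preferable.
* `read_bed` / `read_bedgraph` deliberately implement the strict subsets
  of BED/bedGraph used here (3–6 columns; 4 columns) with line-number
  diagnostics; they are not general-purpose browser-track parsers.
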