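---
title: "Pooled-sequencing variability estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-sequencing variability estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolpop)
```

## The sampling model

Pool-seq sequences a single library made from the DNA of many individuals,
so allele frequencies must be inferred from read counts. Two distortions
separate read counts from the classical per-individual data that
θ-estimators were derived for:

1. **Resampling of chromosomes.** A pool of $n$ chromosomes is sequenced to
   coverage $C$ with replacement: the same chromosome can be read twice.
   Conditional on an allele being carried by $k$ of the $n$ chromosomes, the
   number of reads $m$ carrying it is $\mathrm{Binomial}(C, k/n)$
   (`prob_reads_given_pool()`).
2. **Spectrum truncation.** Sequencing errors masquerade as rare alleles, so
   SNP calling requires a minor allele count of at least $b$ reads. This
   removes the allele-frequency classes outside $b \le m \le C-b$, which the
   estimators must correct for rather than ignore.

Under the neutral expectation that an allele segregates at pool count $k$
with weight $1/k$, each SNP's contribution is divided by the expected yield
of the observable window at that site's coverage:

$$D_W(C) = \sum_{m=b}^{C-b}\ \sum_{k=1}^{n-1} \frac{1}{k}\, P(m \mid k),
\qquad
D_\pi(C) = \sum_{m=b}^{C-b} \frac{2m(C-m)}{C(C-1)} \sum_{k=1}^{n-1}
\frac{1}{k}\, P(m \mid k),$$

giving the windowed estimators
$\hat\theta_W = \sum_{\text{SNPs}} 1 / D_W(C_{\text{site}})$ and
$\hat\theta_\pi = \sum_{\text{SNPs}} h_{\text{site}} / D_\pi(C_{\text{site}})$
(per site after division by the number of covered sites), with
$h = \frac{C}{C-1}\bigl(1 - \sum_a f_a^2\bigr)$ the read-level
heterozygosity. Coverage varies along real data, so the correction is
evaluated at each SNP's own effective coverage and memoised per coverage
(`correction_tables()`).

Two closed forms keep this exact and fast at any coverage: the inner $m$-sum
of $D_W$ is a binomial CDF difference, and the untruncated $\pi$ weight has
expectation $2p(1-p)$ exactly (because $E[m(C-m)] = C(C-1)p(1-p)$), leaving
only $2(b-1)$ tail terms to subtract. Two limits anchor the corrections:
$D_W \to a_{n-1} = \sum_{k<n} 1/k$ as $C \to \infty$ with $b=1$, and
$D_\pi = (n-1)/n$ *exactly* for $b=1$ at any coverage — the classical
denominators of individual sequencing.

The model assumes all individuals contribute equal amounts of DNA to the
pool; unequal contributions are not modelled.

## Tajima's D under truncation

$D = (\hat\theta_\pi - \hat\theta_W)/\sqrt{\widehat{\mathrm{Var}}}$ on the
window-total scale. The variance is a documented reconstruction rather than
an exact finite-sample result: we evaluate the classical Tajima (1989)
constants $a_1 \dots e_2$ at the pool size $n$ and plug in
$S^\ast = a_1\,\hat\theta_W$ — the window's corrected Watterson estimate
back-transformed to an effective segregating-site count — so that
$\widehat{\mathrm{Var}} = e_1 S^\ast + e_2 S^\ast(S^\ast - 1)$. Using
$S^\ast$ instead of the observed SNP count matters because truncation at
$b \ge 2$ under-counts segregating sites, while $\hat\theta_W$ is unbiased
for the full $\theta$. The construction is validated behaviourally: over
many neutral simulated windows the mean $D$ from the pooled pipeline stays
within $\pm 0.3$ of zero (the test suite checks 50 windows at $b=2$,
coverage 50). The sign behaviour (negative for singleton-skewed spectra,
positive for intermediate-frequency excess) follows from the numerator. $D$
is reported as `NA` when a window has no SNPs or a non-positive variance
estimate.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pool_size` | — | chromosomes in the pool (2× individuals for diploids); accuracy of the $1/k$ spectrum weighting assumes a reasonably large pool |
| `min_count` (b) | 2 | minimum reads carrying an allele; 2–3 suppresses most sequencing errors at coverages up to a few hundred |
| `min_quality` | 20 | Phred floor per base call when reading the pileup |
| `min_coverage` | 4 | sites below it are uncovered; must be ≥ 2b (the correction is undefined below, and such sites are always excluded from both numerator and covered-site count) |
| `max_coverage` | ∞ | repeat-region guard; setting a finite bound is recommended on real genomes |
| `window_size`, `step_size` | — | bp; equal for non-overlapping tiling |
| `min_covered_fraction` | 0.6 | windows with fewer covered sites report `NA`; avoids the instability of near-empty windows while keeping most data |

Window statistics divide by the number of covered sites by default
(`normalize = "covered"`); dividing by window length is available
(`normalize = "length"`). Covered-site normalisation is the natural choice
when coverage gaps are alignment artefacts rather than missing sequence.

## Trimming

The modified Mott algorithm scores each base $q_i - Q$ for a quality
threshold $Q$ and keeps the contiguous substring with the maximum score sum,
trimming from either side. Design choices the algorithm statement leaves
open, fixed here deterministically: ties are broken *leftmost, then
longest*; a best sum of exactly zero is a rejection (no informative bases);
`N` bases carry quality 0 and terminal `N` runs are stripped before scoring,
so a threshold of 0 passes reads through except for terminal-`N` removal.
The implementation is an $O(L)$ prefix-minimum scan, tested against
exhaustive enumeration of all substrings.

## Pileup dialect

Classic 6-column SAMtools pileup, 1-based positions. `^` consumes the
following mapping-quality character and `$` is consumed; `+n/-n` indels are
skipped; strands are merged (the estimators are strand-agnostic). `*`
deletion placeholders and `N` calls consume a quality character but never
count as alleles, so they reduce effective coverage — the pileup text does
not state how placeholders should be treated, and exclusion is the choice
made here. Sites whose effective coverage is zero are kept and flagged
uncovered. Triallelic and quadriallelic sites are retained: every allele
with count ≥ b participates, and $h$ naturally covers more than two
alleles; discarding them would waste information.

## Outputs

The wiggle writer emits one `variableStep` block per chromosome with window
*start* coordinates (starts, not midpoints, so that spans tile exactly) and
8-decimal values, omitting undefined windows; the TSV writer encodes them as
`"na"`. Divergence windows report
$d_{xy} = \#\{\text{differing valid columns}\}/\#\{\text{valid columns}\}$
in reference coordinates, gaps and `N` excluded, with no multiple-hit
correction.

## The simulation harness

`simulate_haplotypes()` draws a neutral constant-size sample. The default
study conditions are 400 chromosomes over 100 kb at $\theta = 5\times
10^{-3}$ per site (Drosophila-scale variability), 75 bp reads, per-base
error rates 0.1–1% and target coverages 50–250×, five replicates — the
conditions under which the bias table below is computed. Implementation
choices:

* **Recombination** is approximated by simulating an independent coalescent
  tree per 1 kb block: at the high per-locus recombination rate of the study
  design, distant sites are quasi-independent, and linkage affects the
  variance across replicates, not the estimator bias being measured. A
  direct SFS-sampling mode (`mode = "sfs"`, site counts
  $\mathrm{Poisson}(\theta L / k)$ per derived class $k$) is provided as a
  fully unlinked alternative.
* **Reads are placed at their true positions** and stacked directly into
  per-site counts; mapping is deliberately bypassed, because simulated reads
  are near-identical to their reference and read mapping is not the quantity
  under test. Consequences of mapping bias are outside what these
  simulations can show.
* **The error model** flips each base independently to a uniformly chosen
  different base with probability `error_rate` (no position-in-read trend,
  no error bias towards particular substitutions), and simulated qualities
  are a constant above any filter threshold so the error-rate knob alone
  controls false SNPs. Real Illumina errors are position-dependent and
  partially systematic; the simulations therefore bound what independent
  errors do, not what correlated errors could do.
* Truth values ($\theta_W = S/a_{n-1}$, $\pi$ from pairwise differences,
  classical D) come straight from the haplotype matrix (`truth_stats()`).

`run_bias_experiment()` ties this together: per replicate one haplotype set
is shared across all grid cells, reads are drawn per cell, the full pooled
pipeline (`sliding_windows()` as a single locus-wide window with
`min_coverage = 2b`) is run, and the mean over replicates of
$|o - e|/e$ is reported for $\hat\theta_\pi$ and $\hat\theta_W$ (absolute
deviation for D). At minor allele count 1 even a 0.1% error rate inflates
$\hat\theta_\pi$ several-fold relative to $\theta = 0.005$ — roughly
$2\epsilon/\theta$ from singleton false SNPs — while $b = 2$–3 brings the
deviation down to the few-percent sampling noise for errors up to 0.2%;
raising coverage at fixed $b$ raises the error inflation again. The test
suite and `scripts/acceptance.R` recompute this table at the full study
scale (five replicates of 400 chromosomes × 100 kb; about 20 s on one CPU),
and the smaller property checks use loci of 2–50 kb and pools of 4–100
chromosomes, sizes chosen to keep the whole suite around a minute while
leaving every statistical tolerance at 3 standard errors.

## Numerical notes and degenerate inputs

* Binomial terms use `dbinom`/`pbinom` (log-space internally), stable to
  coverages well beyond 10⁴.
* The denominator cache is keyed by coverage and bounded; it is flushed
  wholesale if it ever exceeds its bound (coverages recur heavily, so in
  practice it never does).
* Sites with $C < 2b$: excluded from the numerator *and* the covered-site
  count — the truncation window is empty there.
* Empty windows: `theta = NA` when no site is covered (distinct from 0,
  which means covered-but-monomorphic); final partial windows are emitted
  and flagged.
* Unsorted pileup input is an error, not a silent misgrouping.

## Limitations

* Equal DNA contribution per individual is assumed; pool-construction
  variance is not modelled.
* The Tajima's D variance is a reconstruction (above), suitable for genome
  scans and rank comparisons; its tail quantiles should not be used for
  formal hypothesis tests without simulation-based calibration.
* Divergence is uncorrected for multiple hits and relies on a supplied
  pairwise alignment; projection through rearrangements is the aligner's
  responsibility.
* No McDonald–Kreitman/HKA-style tests; no per-SNP posterior allele
  frequencies.
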