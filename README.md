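# poolpop

Population-genetic analysis of pooled sequencing (Pool-seq) data in R.

Sequencing a single DNA pool made from many individuals is a cheap way to
estimate genome-wide population parameters, but the classical estimators of
variability cannot be applied to read counts directly: reads sample the
pooled chromosomes *with replacement*, and suppressing sequencing errors by
requiring a minor allele count of at least *b* reads truncates the allele
frequency spectrum. `poolpop` implements bias-corrected estimators of
θ<sub>Watterson</sub>, θ<sub>π</sub> and a Tajima's D adapted to the
truncated spectrum, together with the surrounding workflow: quality trimming
of FASTQ reads (modified Mott algorithm), SAMtools-pileup parsing, SNP
calling, sliding-window genome scans with GTF restriction/masking, windowed
between-species divergence (d<sub>xy</sub>), and a neutral coalescent
simulation harness that quantifies estimator accuracy under sequencing
error.

## The estimators

For a pool of *n* chromosomes sequenced at coverage *C*, the probability
that an allele carried by *k* pool chromosomes appears on *m* of the *C*
reads is binomial:

    P(m | k) = C(C, m) (k/n)^m (1 - k/n)^(C-m)

Under neutrality an allele segregates at pool count *k* with weight
proportional to 1/*k*. Requiring every allele to be seen on at least *b*
reads restricts the observable read counts to b ≤ m ≤ C − b, so each SNP's
contribution is divided by the expected yield of that truncated window:

    θ̂_W  = Σ_SNPs 1 / D_W(C)          D_W(C) = Σ_{m=b}^{C-b} Σ_{k=1}^{n-1} (1/k) P(m|k)
    θ̂_π  = Σ_SNPs h / D_π(C)          D_π(C) = Σ_{m=b}^{C-b} [2m(C-m)/(C(C-1))] Σ_{k=1}^{n-1} (1/k) P(m|k)

where h = C/(C−1) · (1 − Σ<sub>a</sub> f<sub>a</sub>²) is the site
heterozygosity from read-level allele frequencies and each SNP uses the
denominator at its own effective coverage. As C → ∞ with b = 1 these reduce
to the classical denominators a<sub>n−1</sub> = Σ 1/k and (n−1)/n. Tajima's
D is (θ̂_π − θ̂_W)/√Var with the classical variance constants evaluated at
the pool size and θ plugged in from the window's θ̂_W (see the methods
vignette for the exact form and its validation).

## Worked example

Simulate a 50 kb locus for a pool of 100 chromosomes at θ = 0.005/site,
sequence it to 60× with 0.2% base error, and scan it in 10 kb windows with a
minor allele count of 2:

```r
library(poolpop)
set.seed(42)
params <- sim_params(n_chromosomes = 100, locus_length = 50000,
                     theta_per_site = 0.005, error_rate = 0.002,
                     target_coverage = 60)
haps   <- simulate_haplotypes(params)
truth  <- truth_stats(haps)
counts <- simulate_reads(haps, params)
write_pileup(counts, "example.pileup")

pp    <- pool_params(100, min_count = 2, min_quality = 20, min_coverage = 10)
sites <- read_pileup("example.pileup", min_base_quality = pp$min_quality)
win   <- sliding_windows(sites, window_spec(10000, 10000), pp)
```

which prints:

```
   start   end snp_count covered_fraction theta_w theta_pi tajima_d
1:     1 10000       188            0.999 0.00517  0.00473 -0.28700
2: 10001 20000       231            1.000 0.00637  0.00636 -0.00398
3: 20001 30000       204            1.000 0.00559  0.00545 -0.08820
4: 30001 40000       227            1.000 0.00624  0.00553 -0.38300
5: 40001 49999       230            0.999 0.00643  0.00635 -0.04090
```

The per-site estimates scatter around the haplotype truth computed directly
from the simulated sample (θ_W = 0.00537, θ_π = 0.00542 here), and D stays
near its neutral expectation of zero. `write_wiggle()` and
`write_window_tsv()` export the scan for genome browsers; `dxy_windows()`
adds a divergence track from a pairwise aligned FASTA.

A command-line interface wrapping the same functions ships as
`exec/poolpop` with subcommands `trim`, `variance`, `snp-table`, `dxy` and
`simulate`.

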