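---
title: "Composite selection-signature scanning with dcmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite selection-signature scanning with dcmscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmscan)
```

## The problem

Directional selection — natural or breeder-driven — leaves localized
footprints in a population's genome: one haplotype rises in frequency,
local diversity falls, allele frequencies diverge from related
populations, and the site-frequency spectrum is distorted. No single
statistic captures all of these facets, and the classical statistics are
correlated with each other, so naively summing their evidence
over-counts shared information. `dcmscan` implements a per-SNP composite
scan: five statistics are computed per breed, converted to one-tailed
empirical p-values, and combined into a de-correlated composite of
multiple signals (DCMS) whose weights discount statistics in proportion
to their total absolute correlation with the whole set.

## The five statistics

All statistics are computed on the merged post-QC panel, per breed, and
aligned to the same SNP order so that they can be combined per locus.

* **FST (Weir–Cockerham)** — the two-group variance-components estimator
  $\hat\theta = a/(a+b+c)$, contrasting the focal breed against all
  remaining samples pooled. Negative estimates are set to zero (they
  mean "no differentiation", and the composite uses a right tail), and
  the track is smoothed per chromosome with a running median of 31 SNPs
  with constant end rule.
* **Nucleotide diversity (π)** — per site, $2 c_0 c_1 / (n(n-1))$ for
  $c_0$ reference and $c_1$ alternate alleles among $n$ called
  chromosomes; smoothed like FST. Depressed π is evidence of a sweep
  (left tail).
* **Tajima's D** — computed in non-overlapping 300 kb bins (the bin
  width is configurable), each bin's value assigned to all its SNPs;
  bins without segregating sites score 0, the neutral expectation.
  The standardization constants use the modal chromosome count across
  the bin's sites, which equals twice the sample count on complete
  data. Left tail: a post-sweep excess of rare variants drives D
  negative.
* **H1 and H12 (Garud)** — expected haplotype homozygosity of sliding
  windows of 14 consecutive SNPs (step 1) over the breed's phased
  haplotypes: with window haplotype frequencies $p_1 \ge p_2 \ge \dots$,
  $H1 = \sum_i p_i^2$ and $H12 = (p_1+p_2)^2 + \sum_{i\ge3} p_i^2$.
  Right tail. Each window's value is anchored to its 7th SNP
  ($\lceil 14/2 \rceil$); chromosome-end SNPs take the nearest anchored
  value so every SNP carries all five statistics — the combination step
  requires complete tracks. The anchor and edge conventions are package
  choices (any per-SNP alignment needs one); both are config-exposed.

## The composite

For SNP $l$ and statistics $t = 1..n$ with one-tailed p-values $p_{lt}$
and correlation matrix $r$:

$$\mathrm{DCMS}_l \;=\; \sum_{t=1}^{n}
  \frac{\log\!\left[(1-p_{lt})/p_{lt}\right]}{\sum_{i=1}^{n} |r_{it}|}$$

The per-statistic weight factor $1/\sum_i |r_{it}|$ lies in $[1/n, 1]$:
mutually uncorrelated statistics contribute their full logit terms (the
composite is their sum), perfectly correlated statistics are
down-weighted to $1/n$ (the composite is their average). The logarithm
is natural; since the scores are subsequently calibrated against their
own empirical distribution, the base affects only the scale, not the
ranking or the q-values, and it is config-exposed.

Component choices, in order of the pipeline:

* **Fractional-rank p-values.** With ascending fractional ranks $r_l$
  (ties averaged) over $N$ SNPs, left-tail $p = r_l/(N+1)$ and
  right-tail $p = (N+1-r_l)/(N+1)$. The $N+1$ denominator keeps p
  strictly inside $(0,1)$, which the logit requires. π and D use the
  left tail; FST, H1, H12 the right tail.
* **Robust correlation (FAST-MCD).** The correlation among the five raw
  (smoothed) tracks is estimated by the minimum covariance determinant:
  `nsamp` random 6-point subsets are each concentrated by C-steps to
  convergence on the $h = \lceil 0.75\,N \rceil$ points with smallest
  Mahalanobis distance; the minimum-determinant solution is
  consistency-corrected against the $\chi^2_5$ median and reweighted at
  the $\chi^2_5(0.975)$ cutoff, and the reweighted covariance is
  converted to a correlation matrix. When `nsamp` is at least the
  number of possible subsets the search is exhaustive and deterministic;
  otherwise a seed is required, so runs are reproducible. The robust
  estimator keeps the (outlier-rich) selected regions from inflating the
  correlation estimate. `nsamp = 50000` reproduces the reference
  analysis scale; 500 is ample for the five-column problems here and is
  the pipeline default.
* **Calibration.** The genome-wide DCMS vector is fitted by an
  intercept-only Huber M-estimate (tuning constant $k = 1.345$, scale
  re-estimated each iteration as $1.4826 \times$ MAD, convergence when
  the location moves by less than $10^{-8}$ of the scale). Upper-tail
  normal p-values follow from the fitted location and scale, and
  Benjamini–Hochberg q-values control the FDR.

## Region calling and annotation

A run of at least `min_seed = 2` consecutive SNPs with $q < 0.05$ seeds
a region; the region extends outward over SNPs with $q \le 0.1$ and its
boundary is the last such SNP (the first flanking SNP with $q > 0.1$ is
excluded; an inclusive-boundary flag selects the alternative reading).
Overlapping extensions merge, the peak being the overall minimum-q SNP.
`min_seed` defaults to 2 because a single-SNP "run" is not a run of
consecutive SNPs; it is config-exposed. Protein-coding genes overlapping
a region are ranked by the distance from the region's peak SNP to the
nearest gene edge (0 inside the gene), ties broken by genomic start —
rank 1 is the closest gene to the most significant SNP.

## Quality control

SNP and sample filters run per breed group in a fixed order — duplicate
ids and sex/unplaced chromosomes, sample call rate $\ge 0.95$, SNP call
rate $\ge 0.95$, MAF $\ge 0.05$, HWE $\chi^2$ p $\ge 10^{-6}$ (the plain
1-df test, not the exact test) — and the groups are merged on mutual
SNPs with a strand-safe allele check. The report tallies removals per
step, so counts are additive and the filter is idempotent. Population
structure is summarized by the identity-by-state matrix (mean shared
alleles per genotype pair / 2), double-centered and eigen-decomposed;
a sample farther than `outlier_z = 3` robust SDs (per-axis median/MAD in
the PC1–PC2 plane) from its breed centroid is flagged and removed. The
z-rule is an explicit, deterministic stand-in for the visual
cluster-outlier screen common in array studies, which is rarely stated
as a formula; both the threshold and the step itself are configurable.

## The simulator

`sim_config()`/`simulate_scan_dataset()` implement a forward
Wright–Fisher model: an ancestral pool of $2N_e$ haplotypes is
initialized site-wise from a neutral-like frequency law (density
$\propto 1/f$ truncated to $[1/(2N_e),\, 1 - 1/(2N_e)]$), evolved
through a burn-in (default 100 generations) to build linkage
disequilibrium, then split into populations that drift independently.
Each offspring haplotype is a recombinant of one parent's two
haplotypes (crossovers Poisson with rate = per-bp rate × length,
positions uniform; default $10^{-8}$/bp ≈ 1 cM/Mb), parents drawn
proportionally to fitness $1, 1+hs, 1+s$ ($h = 0.5$) at the focal SNP
of any active sweep. There is no recurrent mutation — variation enters
only through the initial frequencies — which is sufficient for sweep
footprints over the short horizons simulated and keeps the model
minimal. Hard sweeps can start from standing variation (`mode =
"standing"`, focal frequency pinned at initialization, default 0.1, the
conventional standing-sweep starting point) or from a single de-novo
copy introduced on one haplotype at the split (`mode = "de_novo"`), the
classic hard-sweep origin. Survival conditioning
(`condition_on_sweep_survival`) re-draws a swept population's post-split
evolution until the allele survives; it is off by default so neutral
behaviour is unbiased, and losses are recorded in the truth table.

What the generator emulates: multi-population divergence from a common
ancestor, LD from recombination and drift, array-like ascertainment
(through the QC MAF filter), and hard-sweep footprints with known truth.
What it does not emulate: new mutations (so post-sweep diversity cannot
regrow and the rare-variant excess behind negative Tajima's D is
muted), gene conversion, variable recombination maps, ascertainment
toward a discovery panel, and genotyping error. Passing tests therefore
demonstrate the pipeline's mechanics and its behaviour under drift and
sweeps, not calibration on real array data.

## Power under strong drift: a known limitation

The recovery benchmark in the test suite simulates two populations of
$N_e = 200$ diverging for 150 generations with one conditioned de-novo
sweep ($s = 0.1$) among 3000 SNPs on 30 Mb, and asks whether a
$q < 0.05$ region covers the focal SNP. At these parameters only some
10–25% of replicates (depending on the seed batch) are recovered, and
the bottleneck is structural
rather than numerical: after $t/2N_e \approx 0.38$ coalescent units of
divergence plus MAF/HWE ascertainment, over a tenth of the genome is
drift-fixed within a breed, so the smoothed tracks saturate — H12 = 1,
π = 0 and FST at its clipped plateau over large background stretches.
Fractional ranks average over these ties, capping each statistic's
p-value near the tied fraction, and the composite of a genuine sweep
cannot exceed the drift plateau even when its footprint is
textbook-perfect (verified on completed $s = 0.3$ sweeps). The same
replicates are recovered decisively ($q \approx 0$) whenever the
footprint does exceed the plateau. In regimes with milder drift (larger
$N_e$, shorter divergence, denser polymorphism) the plateau shrinks and
recovery rises; the neutral false-positive behaviour — median zero
called regions — holds throughout.

## Numerical choices and degenerate inputs

* Ties in rank p-values get mean ranks; all p stay strictly in (0,1).
* A statistic track with zero spread aborts the MCD with a
  `degenerate statistics` error rather than returning a meaningless
  correlation; a constant DCMS vector likewise aborts the Huber fit.
* Monomorphic sites: HWE p = 1, π = 0; bins without segregating sites
  take D = 0; windows whose haplotypes all contain missing alleles are
  an error, while individual missing-containing haplotypes are dropped
  and frequencies renormalized.
* Tajima's D bins follow the left-closed grid `[0, b), [b, 2b), ...`
  in base pairs; position transforms that preserve bin membership leave
  D unchanged.
* The running median returns the whole-vector median when the window
  exceeds the vector length.
* Stage seeds derive deterministically from the master seed
  (`child_seed`), so per-breed MCD subsampling and the simulator are
  independently reproducible and the whole scan is a pure function of
  (inputs, config, seed).

## Problem sizes used in the tests

Module tests run on panels of tens to hundreds of SNPs and oracle
batteries of 200 randomized small instances per statistic; the
end-to-end recovery protocol runs 20 sweep and 10 neutral scans at the
3000-SNP scale with `nsamp = 500` MCD starts. These sizes exercise every
code path — including per-chromosome smoothing, bin assignment and
region merging — while keeping a full suite run in minutes on one core.
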