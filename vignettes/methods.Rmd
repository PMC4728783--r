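---
title: "Methods: HMR segmentation and super-enhancer methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HMR segmentation and super-enhancer methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`semethyl` analyses CpG-resolution whole-genome bisulfite sequencing (WGBS)
methylomes. The unit of data is the pair of methylated/unmethylated read
counts at a CpG; a sample is an ordered table of such sites
(`methylome()`). All internal coordinates are 0-based half-open; 1-based
conventions exist only at file boundaries (Bismark-style coverage files).
Zero-coverage CpGs are retained but their raw level is undefined (`NA`);
each downstream operation states its own handling. Symmetric-CpG strand
pooling (`merge_strand_counts()`) is provided but optional, since published
HMR-calling pipelines differ on whether strands are pooled; pooling is
greedy left-to-right on adjacent positions and keeps the plus-strand
coordinate.

# Smoothing

The smoothed methylation level is a degree-0 local-likelihood fit: a
tricube-kernel, coverage-weighted binomial mean over the CpGs within
`half_window` (default 500 bp) of each site,

$$\hat m_i = \frac{\sum_j w_{ij}\,k_j}{\sum_j w_{ij}\,n_j},
\qquad w_{ij} = \left(1 - (d_{ij}/h_i)^3\right)^3 .$$

Windows expand symmetrically (one site per side per step) until they hold at
least `min_cpgs` sites (default 10); when a window expands, the kernel
radius grows to the furthest included site plus 1 bp so every member keeps
positive weight. Chromosomes are never mixed.

Degree 0 was chosen deliberately over a higher-degree polynomial fit: it is
exactly testable by a closed-form weighted mean, preserves $[0,1]$ without
clipping, reproduces constant input exactly, and is monotone in the
methylated counts. The cost is a small attenuation of sharp boundaries,
which does not matter downstream because boundary detection is done by the
HMM on raw counts, not on smoothed levels. Bandwidth and window defaults
are of the order used by established WGBS smoothers; results that depend on
them (profile shapes, the large-HMR candidate filter) should be read as
qualitative.

# HMR segmentation

Hypomethylated regions (HMRs) are called by a two-state (low/high
methylation) hidden Markov model with beta-binomial emissions on the raw
counts,

$$P(k \mid n, \alpha, \beta) = \binom{n}{k}
\frac{B(k+\alpha,\, n-k+\beta)}{B(\alpha, \beta)},$$

fitted by Baum–Welch EM on covered sites. Choices that were genuinely open
and how they were resolved:

* **Chain breaks.** The observation sequence restarts from the initial
  distribution at chromosome ends and at CpG gaps larger than `gap_bp`
  (default 5 kb). Without breaks, transition probabilities across megabase
  gaps would be meaningless.
* **M-step.** The emission shapes maximize the expected beta-binomial
  log-likelihood by bounded numerical optimization (L-BFGS-B in log space,
  shapes confined to $[10^{-3}, 10^4]$), warm-started from the previous
  iterate. The bound is not cosmetic: for shape parameters of order
  $10^{20}$ the difference of `lgamma` terms loses all floating-point
  precision and fakes a likelihood near 0, which an unbounded optimizer
  will find.
* **Initialization.** State means 0.2/0.8 at precision 10, self-transitions
  0.9. Convergence at relative log-likelihood change below `tol` (default
  1e-4) or `max_iter` (default 100). States are re-ordered at the end so
  mean(low) < mean(high).
* **Decoding.** Posterior (per-site argmax) decoding by default; Viterbi is
  a config switch. Maximal runs of low-state CpGs, not crossing chain
  breaks, become HMRs spanning first to last member CpG (+1).

Each HMR is scored $S = n - \sum_i m_i$ (CpG count minus the sum of raw
per-site levels; zero-coverage sites are not decoded and therefore not
members). Regions are filtered against a permutation null: the count pairs
are shuffled across site positions genome-wide, the methylome re-decoded
under the fitted parameters, and null region scores pooled over
`n_permutations` (default 20) replicates; the cutoff is the pooled scores'
99th percentile under the linear-interpolation (R type 7) quantile
definition, and only regions with score strictly above it survive. Whether
the original procedure permuted within chromosomes and how many permutations
it used is not stated anywhere we could find; both are config knobs, and a
global shuffle with full re-decoding preserves the segmentation null.

# Large HMRs

Large HMRs are found per sample by the rank-scaling construction used for
super-enhancer calling from histone signal: candidates are HMRs with mean
smoothed level < 0.2; sizes are sorted ascending and mapped to the unit
square by $x_i = (i - 0.5)/n$ (the half-offset keeps $\mathrm{logit}(x)$
finite at both ends, which the bare 0–1 mapping does not) and
$y_i = s_i / s_{\max}$. An OLS line of $\log y$ on $\mathrm{logit}(x)$ is
fitted over the regions above the 90th size percentile, and the cutoff
$x^\*$ solves

$$\frac{d}{dx}\, e^{a + b\,\mathrm{logit}(x)}
 = e^{a + b\,\mathrm{logit}(x)}\frac{b}{x(1-x)} = 1$$

by a sign-scan plus bisection on $(0.5, 1)$, keeping the largest root
(multiple roots can occur for some fits; "above this point" implies the
upper tangent). Regions with $x > x^\*$ are large.

A known limitation, established by simulation and reflected in one
deliberately red acceptance check: on a smooth lognormal size background
with a small population of ten-fold larger implants, the procedure recovers
essentially all implants but also flags roughly 3–5 % of the background —
the fitted log-logit curve cannot represent the jump at the implant
boundary, so its slope-1 point lands below the gap. Users should treat the
large-HMR set as enriched for, not identical to, the outlier population.

# Super-enhancer methylation

Super-enhancers (SEs) are inputs (BED intervals from an external
catalogue). Each SE of length $L$ is extended by $L/2$ on both sides and
positions map linearly to a scaled coordinate: center 0, original edges
±1, extended edges ±2 (odd $L$: floor left, ceil right; extensions clipped
at position 0 keep the unclipped map). Profiles take the smoothed level of
every CpG in the extended region; the SE's average methylation is the
unweighted mean over CpGs strictly inside, binned into four categories at
0.25/0.50/0.75 (left-closed, matching "< 25 %"-style cutoffs).

HMR occupancy is the base-pair fraction of the SE covered by the union of
called HMRs. (A CpG-fraction occupancy was considered and rejected as the
default: "proportion covered" reads most naturally as genomic coverage; the
choice only matters for very uneven CpG densities.) Differential
methylation between a cancer sample and its matched normal is
$\delta = \mathrm{occ}_{\text{cancer}} - \mathrm{occ}_{\text{normal}}$,
labelled hypomethylated when $\delta > 0.25$, hypermethylated when
$\delta < -0.25$ (strict inequalities; positive $\delta$ = methylation
loss). Tissue specificity uses absolute occupancy > 0.20 plus a > 0.10
margin over the *mean* of the other tissues — the mean being the least
extreme summary where the original is silent ("max" is a switch). The
flank-versus-inside reduction $r = \bar m(\text{flanks}) -
\bar m(\text{inside})$ is compared between paired samples with a two-sided
paired t-test: a global methylation shift leaves $r$ unchanged, a focal
SE-targeted shift increases it. Array validation averages beta values over
an SE's probes (at least 3), t-tests target versus remaining samples,
adjusts by Benjamini–Hochberg across SEs, and requires target mean < 0.33
with FDR < 0.05.

# Association statistics

CpGs (and 50-bp windows) classify as hypomethylated below 0.33 and
hypermethylated above 0.66, both strict. The named tests are implemented
directly so that their algorithmic details are fixed and reproducible
rather than implementation-defined:

* **Fisher's exact test**: two-sided p as the sum of hypergeometric
  probabilities of all tables (margins fixed) no more probable than the
  observed one; odds ratio as the cross-product, with the Haldane +0.5
  correction only when a cell is zero. The conditional-MLE odds ratio
  (what `fisher.test` reports) differs slightly; the cross-product form is
  a reproducible closed form.
* **Wilcoxon rank-sum**: midrank ties; exact enumeration of all
  $\binom{N}{n_1}$ assignments when $n_1 + n_2 \le 12$, otherwise normal
  approximation with tie correction.
* **Spearman**: Pearson correlation of midranks; exact full-permutation p
  when $n \le 8$, otherwise the t approximation.
* **BH-FDR**: the explicit step-up $q_i = \min_{j \ge i}(n p_j / j)$.

The exact/approximate switchover points are fixed constants, not tuning
parameters. Windowed histone association tiles a region with 50-bp windows
(terminal remainder kept but flagged), averages ChIP-versus-input signal
(bp-weighted) and smoothed methylation (per CpG) per window, and fits
signal ~ status + CpG density by OLS. Target genes are the closest TSS
within 1 Mb measured from the SE boundary (distance 0 inside; ties to the
smaller coordinate); the expression model is OLS of $\log(\text{expr}+1)$
on average SE methylation — the +1 offset guards zeros the log-linear
formulation is otherwise silent about.

# Synthetic data: what it emulates and what it does not

The generator states a fixed world anchored to the study design the package
targets: CpGs at geometric gaps of mean 100 bp; coverage Poisson(14)
(typical WGBS CpG coverage); background beta-binomial mean 0.75 (normal
tissue global methylation is ~70 %) and HMR mean 0.10; precision
$\alpha+\beta = 30$, giving per-site level sd ≈ 0.12 at coverage 14 —
mild overdispersion over binomial noise, which at this coverage already
contributes sd ≈ 0.1. True HMRs have exponential spacing (mean 30 kb) and
lognormal lengths (mean 1.5 kb). SEs (default 10 kb) cycle through the four
methylation categories with hypomethylated segments anchored at the SE
edges (plus a 5 %-of-length outward lip so the profile minimum falls at the
scaled edges); the Q4 (fully methylated) category raises its local
background to 0.85 so its average stays in the top bin with no implanted
HMR. The cancer shift drops the background mean by 0.075 (global losses of
3–13 percentage points are typical of the matched tumor samples the design
mirrors) and applies focal occupancy changes of ±0.4 to 30 % of SEs.
Histone signal is $5(1-\bar m)$ plus Gaussian noise per 50-bp window;
expression is $\exp(2 - 3\bar m)$ times lognormal noise.

Recorded truth intervals are snapped to the extent of the CpGs they contain
(first to last member CpG + 1): count data carry no information between
CpGs, so the un-snapped extent is unrecoverable by any caller and would
only add irreducible boundary slack to every benchmark.

Every generator call derives its RNG stream from the config seed plus a
small op-specific offset, so individual generators are deterministic and
two samples from one config are independent.

The generator does **not** emulate: read-level error, bisulfite conversion
failure, mappability gaps, CNV, subclonal heterogeneity, correlated
coverage (GC waves), or partially methylated domains. A green recovery test
therefore establishes that the algorithms invert the generative model they
assume — not that they are robust to every artifact of real libraries.

# Numerical and reporting conventions

Forward–backward uses per-position scaling; likelihood agrees with
exhaustive path enumeration to 1e-10 on short chains. The tangent root is
bisected to 1e-8 after a 4096-point sign scan. Empirical quantiles are
R type 7 everywhere. Reported percentages use round-half-up at one decimal
(base R's round-half-even does not reproduce published tables). Pipeline
runs serialize their config next to their outputs and are byte-identical
for identical config and seed.
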