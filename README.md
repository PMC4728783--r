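# semethyl

DNA methylation analysis of super-enhancers from whole-genome bisulfite
sequencing (WGBS), for epigenomics researchers studying how regulatory DNA
loses or gains methylation in cancer.

Large enhancer clusters ("super-enhancers") that drive cell-identity genes
carry characteristic DNA methylation footprints: focal **hypomethylated
regions (HMRs)**, often at the enhancer edges, whose extent tracks enhancer
activity. `semethyl` implements the full quantitative workflow around that
observation:

* **Segmentation.** A two-state hidden Markov model with beta-binomial
  emissions on the raw per-CpG counts, `P(k | n, α, β)`, fitted by
  Baum–Welch EM, segments a methylome into low/high methylation states.
  Maximal low-state runs become HMRs, each scored
  `S = n − Σ mᵢ` (CpG count minus the sum of the raw methylation levels),
  and filtered at the 99th percentile of a permutation null obtained by
  shuffling count pairs across positions and re-decoding.
* **Smoothing.** A tricube, coverage-weighted local-likelihood smoother
  gives per-CpG smoothed levels for profiles and filters.
* **Super-enhancer quantification.** Each SE is extended by 50 % of its
  length on both sides and mapped to a scaled coordinate (center 0, edges
  ±1, extended edges ±2); methylation categories (Q1–Q4 at 0.25/0.50/0.75),
  **HMR occupancy** (bp fraction covered by HMRs) and its cancer-minus-normal
  differential **δ** (|δ| > 0.25 ⇒ hypo-/hypermethylated call), tissue
  specificity (occupancy > 20 % and > 10 % above the other tissues), and a
  paired flank-versus-inside reduction test separating focal from global
  methylation loss.
* **Large HMRs.** Rank-scaled sizes (x = (i−0.5)/n, y = size/max) with an
  OLS fit of log y on logit x over the top size decile; regions above the
  point where the fitted curve's derivative equals 1 are "large".
* **Association statistics.** Fisher's exact test (hypergeometric
  enumeration), Wilcoxon rank-sum (exact ≤ 12), Spearman (exact ≤ 8),
  50-bp-window histone–methylation models, closest-TSS target assignment
  within 1 Mb, log-linear expression models, BH-FDR.
* **Synthetic data.** A fully seeded generator emulating WGBS counts with
  hidden two-state segmentation, SEs with unmethylated edges, cancer shifts
  (global + focal), correlated histone tracks and anti-correlated
  expression — with ground truth, so every stage is benchmarked end to end.

## Worked example

```r
library(semethyl)

cfg  <- sim_config(seed = 42, n_chroms = 1, chrom_len = 1e6, n_ses = 10)
ds   <- simulate_dataset(cfg)                    # paired normal/cancer world
hcfg <- hmr_call_config(seed = 42, n_permutations = 10)

hmrs_n <- call_hmrs(ds$normal, hcfg)
hmrs_c <- call_hmrs(ds$cancer, hcfg)
head(hmrs_n, 3)
#>   chrom start   end n_cpgs  mean_meth    score
#> 1 chrS1 10363 21044     95 0.08171934 87.23666
#> 2 chrS1 35532 38360     34 0.08241299 31.19796
#> 3 chrS1 43669 46465     19 0.10365725 17.03051

ese <- extend_and_scale(ds$ses)
dd  <- delta_occupancy(se_occupancy(ese, hmrs_c, "cancer"),
                       se_occupancy(ese, hmrs_n, "normal"))
dd[dd$label != "unchanged", ]
#>    se_id occ_normal occ_cancer   delta           label
#> 2 SE_002     0.4691     0.8650  0.3959  hypomethylated
#> 4 SE_004     0.0000     0.3646  0.3646  hypomethylated
#> 5 SE_005     1.0000     0.5898 -0.4102 hypermethylated

composition_report(c(altered = sum(dd$label != "unchanged")), total = nrow(dd))
#>     label count total percent
#> 1 altered     3    10      30
```

The segmentation recovers 38 HMRs in the normal sample (null score cutoff
3.05); three of the ten simulated super-enhancers carry a focal occupancy
shift beyond the ±0.25 threshold — exactly the three the generator
implanted (δ ≈ ±0.4), while the global 0.075 background loss alone flags
nothing. `run_pipeline(run_config(outdir = "out", seed = 42))` chains all
stages (simulate → smooth → hmr → se-profile → se-diff → large-hmr →
associate → report) and writes coverage/BED/TSV outputs plus a
`summary.json`.

## Layout

```
R/                  implementation (I/O, smoothing, HMM, large HMRs,
                    SE methylation, statistics, simulator, pipeline/CLI)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/methods.Rmd   model, assumptions, design choices, limitations
inst/cli/semethyl   command-line wrapper
```
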