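---
title: "Drug-target Mendelian randomization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Antihypertensive drugs act by modulating specific protein targets; whether
long-term pharmacological lowering of systolic blood pressure (SBP) affects
pain conditions is hard to study observationally because drug use is
confounded by indication. Drug-target Mendelian randomization (MR)
sidesteps this by using common variants in or near a drug's target gene(s)
as instruments: a variant that lowers SBP through the same protein the
drug inhibits mimics a small, lifelong dose of that drug.

The package implements the full two-sample summary-statistic pipeline:

1. **Instrument construction** per drug class: genome-wide significant SBP
   variants (p < 5×10⁻⁸) within ±100 kb of a target gene, thinned by
   greedy LD clumping so retained pairs satisfy r² < 0.1, with palindromic
   (A/T, G/C) variants excluded and LD proxies (r² > 0.80) substituted for
   instruments missing from an outcome dataset.
2. **A positive-control gate**: instrument sets must show a significant,
   protective association with coronary artery disease (CAD) per 1 mmHg
   SBP decline before they are trusted as antihypertensive proxies.
3. **Estimation** per class × outcome: the Wald ratio
   β̂ = β_out/β_exp for a single SNP, otherwise the inverse-variance
   weighted (IVW) estimator — the zero-intercept weighted regression of
   outcome on exposure effects with weights 1/se²_out. Effects are
   reported as odds ratios per 1 mmHg SBP *decline* (exposure betas are
   negated before estimation), with 95% CIs at ±1.959964 SE and two-sided
   normal p-values.
4. **A sensitivity battery**: Cochran's Q; the multiplicative
   random-effects (MRE) scaling of the IVW SE by √max(Q/(k−1), 1);
   MR-Egger regression, whose intercept tests directional pleiotropy;
   MR-PRESSO global, outlier and distortion tests; the Steiger
   directionality test; and leave-one-out analysis.
5. **Multiple-testing tiers**: the Bonferroni threshold is the family α
   divided by the number of classes *originally tested* (0.05/12 ≈ 0.0042
   in the twelve-class design), "strong" below it, "suggestive" in
   [threshold, 0.05), "none" otherwise.

The three MR assumptions — relevance, independence from confounders, and
exclusion restriction (no path to the outcome except through the
exposure) — map onto concrete checks: per-SNP F-statistics with the F > 10
weak-instrument rule for relevance, a confounder blocklist for
independence, and the Egger/PRESSO pair for exclusion-restriction
violations.

## What the simulator emulates

`simulation_config()` / `simulate_pair()` generate exposure/outcome
summary-statistic pairs with known truth:

* **Cis architecture.** True exposure effects exist only for SNPs inside
  gene windows; null SNPs sit far from every window. Selected instruments
  therefore lie inside windows with probability 1, which the tests exploit.
* **Instrument strength.** Each causal SNP's true noncentrality (expected
  χ²) is drawn uniform on [40, 70], putting single-SNP F-statistics in the
  tens — the regime typical of cis blood-pressure instruments. Strength is
  therefore controlled on the z-scale, not the raw-beta scale, so it is
  stable across sample sizes.
* **Standard errors.** se = 1/√(2·n·eaf·(1−eaf)), the usual
  summary-statistic approximation; effect-allele frequencies are uniform
  on [0.05, 0.5], avoiding degenerate frequencies.
* **LD.** Block-diagonal: each gene's SNPs form one positively-phased
  block with pairwise r² = `ld_block_r2`, realised as equicorrelated noise
  (correlation √r²) and proportionally shared true effects. This is
  sufficient to exercise clumping and proxy lookup; it is not a haplotype
  model.
* **Outcome model.** On the log-odds scale directly:
  β_out = `true_effect`·β_exp(true) + direct effect, the latter drawn for
  a configurable fraction of instruments (the exclusion-restriction
  violators). Direct effects are oriented on the *exposure-raising*
  allele, so directional pleiotropy (non-zero mean) survives the sign
  orientation MR-Egger applies; with a zero mean the Egger intercept stays
  centred on zero.
* **Palindromes.** A configurable fraction of variants get A/T or G/C
  alleles; harmonization must drop them.
* **Multiple outcomes.** `simulate_outcome()` draws further outcome tables
  over the same variants, optionally with per-gene causal effects — the
  drug-target reading in which modulating different targets affects
  different outcomes.

What it does **not** model: individual-level genotypes, case-control
ascertainment, winner's curse, sample overlap between exposure and outcome
GWAS, population stratification, or realistic genome-wide LD. Passing
tests on this generator shows the estimators and the pipeline logic are
correct under the stated generative model — not that real-data results are
unbiased against these unmodelled features.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| p threshold | 5e-8 | genome-wide significance for candidates |
| window | ±100 000 bp, inclusive | cis proximity to a target gene |
| clump r² | < 0.1 (strict) | maximal pairwise LD among instruments |
| proxy r² | > 0.80 (strict) | minimal LD for an outcome-side proxy |
| gate α | 0.05 | CAD positive-control significance |
| family α / classes | 0.05 / 12 | Bonferroni threshold (displays as 0.0042) |
| PRESSO nsim | 1000 | parametric null draws (add-one p-values) |
| CI multiplier | 1.959964 | normal-theory 95% intervals |

Window arithmetic is inclusive at both edges (the conservative reading of
"±100 kb"); both LD thresholds are strict inequalities; palindromic SNPs
are always dropped rather than frequency-rescued.

## Numerical and design choices

* **Clumping determinism.** Candidates are ordered by p-value with ties
  broken by lexicographically smaller variant id, making the greedy result
  invariant to input row order. Unknown LD pairs count as unlinked
  (reference-panel sparsity) and are implicitly auditable from the LD table.
* **MRE floor.** The random-effects scale factor is floored at 1:
  underdispersion never narrows an interval. The same floor applies to the
  Egger residual scale.
* **IVW without an intercept** and without second-order weights is the
  standard estimator; `lm(y ~ 0 + x, weights = 1/se²)` reproduces its
  point estimate exactly, which the test suite uses as an independent
  oracle (the package computes the closed form itself).
* **MR-PRESSO.** The observed residual sum of squares uses leave-one-out
  IVW slopes; the null is parametric (each SNP redrawn around its
  leave-one-out prediction), with leave-one-out slopes recomputed on every
  simulated dataset, vectorised over simulations. P-values use
  (1+b)/(nsim+1). Outlier flagging (Bonferroni-adjusted per-SNP empirical
  p-values) requires k ≥ 4; the distortion test bootstraps outlier-free
  subsets (default 1000 draws — no standard size exists, so it is
  configurable). Outlier-corrected estimates are reported alongside, never
  instead of, the primary estimate.
* **Steiger** compares aggregate variance explained, Σ z²/(z²+n), on the
  Fisher-z scale with sampling variances 1/(n−3) — one directionality
  decision per analysis, not per-SNP voting. An exact tie yields
  "not established" with p = 1.
* **Proxy phase.** The LD table carries r² only, so the sign of the
  correlation between a proxy and its index SNP is unknowable from the
  shipped inputs; proxies' outcome effects are used as reported under a
  positive-phase assumption, and palindromic proxies are never used. The
  simulator generates positively-phased blocks, consistent with this
  limitation; with real data, a phased reference panel would be needed to
  do better.
* **Harmonization actions** are recorded per record (`kept_as_is`,
  `allele_flipped`, `dropped_palindromic`, `dropped_missing`,
  `dropped_mismatch`); dropped records carry no effect estimates
  downstream. Strand-complement configurations are resolved before
  declaring a mismatch.
* **Gate direction.** The CAD gate requires protective direction
  (OR < 1 per 1 mmHg decline) in addition to significance: a
  harmful-direction hit would contradict the premise that the instruments
  proxy antihypertensive action. The gate α of 0.05 is a configurable
  default.
* **Bonferroni denominator.** The number of classes originally tested
  (twelve), not the number surviving the gate — removing a class from the
  panel never changes another cell's estimate, only the threshold.
* **Suggestive band.** The threshold itself is assigned to the suggestive
  tier ([α_bonf, 0.05)); whether the boundary is inclusive is ambiguous in
  common usage, and the package documents this strict-at-the-top choice.
* **Whether clumping precedes or follows the window filter** is
  under-determined in common practice; the package filters to the class's
  pooled cis candidates first and clumps within them.
* **Calibration studies** (`ivw_calibration()`) default to the
  fixed-effect IVW model: the generator's instruments are homogeneous
  under the null, so the fixed model is the calibrated reference and the
  MRE floor is strictly conservative there. The MRE model remains the
  primary scan estimator.

## Operating characteristics the package verifies about itself

The test suite and `scripts/acceptance.R` re-derive, from fresh
simulations at 20 instruments and n = 100 000 per study:

* IVW type-I error at α = 0.05 under the null, and 95% CI coverage and
  mean bias at a true effect of 0.1 (500 replicates each);
* MR-PRESSO recovery of two injected 8·SE outliers among 20 instruments
  (both flagged, at most one false positive; 50 replicates at nsim = 1000);
* Steiger's correct-orientation rate when instruments explain an order of
  magnitude more variance in the exposure (200 replicates);
* equality of instrument selection with a brute-force filter, and per-SNP
  F-statistics in the tens at the simulator's defaults.

These replicate counts are the package's validation sizes; the analysis
drivers under `analysis/` run the same studies at presentation sizes and
write their tables under `results/`. No empirical claim is made in this
vignette that those scripts do not themselves compute.

## Known limitations

* Two-sample MR conventions throughout: no t-corrections, no
  second-order/exact weights, no weighted-median or mode estimators, no
  multivariable MR.
* The confounder screen is a local blocklist file; it is only as good as
  the list supplied.
* Binary-outcome effects are treated as log odds ratios supplied by the
  outcome GWAS; no liability-scale conversion is attempted.
* The simulator's LD and effect-size models are deliberately minimal (see
  above); estimates of, e.g., clumping behaviour under realistic LD decay
  require real reference panels.
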