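---
title: "Methods: cis-pQTL MR with pairwise conditional colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-pQTL MR with pairwise conditional colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pqtlmr)
```

This vignette documents the statistical model behind each stage of the
package, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the design decisions taken
where the methodology admitted more than one reading.

## The screen

The pipeline asks, for each circulating protein with cis-pQTL
instruments, whether genetically predicted protein level causally affects
an outcome trait. Stages: instrument selection → two-sample MR →
Bonferroni screen → pairwise conditional colocalization for the
significant proteins only. The colocalization gate matters because an MR
association can be produced by LD confounding: the protein's cis variant
may sit in LD with a distinct causal variant for the outcome without any
causal role for the protein itself.

## Instrument selection

A SNP is a candidate instrument when it (i) lies within the cis window of
the protein's gene, (ii) passes the instrument significance threshold on
the exposure association, (iii) is not protein-altering (a
protein-altering variant can change the measured epitope rather than the
protein's level, violating the exclusion restriction), (iv) has
MAF > 1 % (strict inequality), and (v) is present in the outcome GWAS.

Parameters, with units and defaults:

| parameter      | default | meaning |
|---------------|---------|---------|
| `cis_window`  | 1 Mb    | closed window around the gene's TSS; field convention for cis-pQTLs |
| `p_threshold` | 5e-8    | genome-wide significance, the standard for published cis-pQTLs |
| `maf_min`     | 0.01    | "MAF above 1 %" read strictly: min(EAF, 1−EAF) > 0.01 |
| palindromic band | [0.45, 0.55] | inclusive at the endpoints (the inclusive reading was chosen; the band's endpoints are ambiguous in common usage) |
| `r2_threshold` | 0.01   | greedy LD pruning, keeping the most significant pQTL |

Harmonization aligns both traits to one effect allele: swapped allele
labels negate the outcome beta and reflect its frequency; strand-flipped
non-palindromic pairs are aligned by complementing; palindromic SNPs
retained outside the ambiguity band are oriented by requiring both
frequencies to fall on the same side of 0.5, and are dropped when the
outcome frequency is itself inside the band. LD pruning is fully
deterministic: candidates are ordered by exposure p, ties by |z|
descending, then snp_id, so reruns are reproducible. Every excluded SNP
carries a reason code and retained + excluded partition the input — a
property the test suite asserts.

## MR estimator

With one instrument the Wald ratio is used: θ̂ = β_out/β_exp,
se = se_out/|β_exp| (first-order delta method, ignoring the exposure SE —
the conventional default of the standard implementations; a second-order
option exists behind `second_order = TRUE`). With k > 1 instruments the
per-SNP ratios are combined by inverse-variance weighting. Cochran's
Q = Σwⱼ(θ̂ⱼ−θ̂)² on k−1 df decides the variance model: when the Q test
p-value falls below `het_alpha` (default 0.05 — the heterogeneity alpha is
not dictated by the methodology, 0.05 is the natural reading and is
recorded in the result object), the random-effects SE is reported as the
fixed SE times √max(1, Q/df). This is the *multiplicative* random-effects
dialect, not an additive between-instrument variance component; it never
deflates the SE below the fixed-effects value. P-values are two-sided
normal tails computed on the upper-tail log scale so extreme signals
yield exact tiny values rather than 0.

The Bonferroni threshold is α divided by the number of proteins that
actually had ≥ 1 valid instrument (not the number supplied); proteins
with no instruments are reported as `not_testable` rather than dropped.

## Colocalization

Per SNP, the Wakefield approximate Bayes factor against the null uses
prior effect standard deviation 0.15 for quantitative traits (per-SD
scale) and 0.2 for binary traits (log-odds scale) — the conventional
defaults, configurable per trait. Hypothesis weights over a region of Q
SNPs use per-SNP priors p1 = p2 = 1e-4 and p12 = 1e-5 (again the
method's conventional defaults; the priors actually used are recorded in
every result object). All sums and products of ABFs are accumulated with
log-sum-exp; the H3 term S1·S2 − S12 is computed as a log-space
difference clamped at ≥ 0 against rounding, and is exactly 0 for a
single-SNP region. Posteriors sum to 1 within 1e-12 by construction and
this is asserted in every acceptance evaluation.

## Conditional analysis from summary statistics

The COJO-style machinery reconstructs joint fits from marginal GWAS
statistics plus a reference LD panel: D_j = 2f_j(1−f_j)n_j approximates
the centered genotype sum of squares, (X'X)_{ij} ≈ r_ij√(D_iD_j),
(X'y)_j = D_j b_j, and the regional phenotypic sum of squares Syy is the
median over SNPs of D_j(b_j² + (n_j−2)se_j²) — the median makes the
estimate robust to occasional mis-scaled SNPs. The effective sample size
is the median per-SNP N. Conditional statistics for SNP i given a set S
are obtained by refitting S ∪ {i}; this is mathematically identical to
the two-block algebra and much easier to validate against the
individual-level oracle. SNPs with reference r² above the collinearity
cutoff (default 0.9) to the conditioning set are flagged and assigned
conditional beta 0 with marginal SE, excluded from signal searches.
Stepwise selection starts at the minimum-p SNP, admits the best
conditional candidate below `p_cutoff` (default 5e-8), drops selected
SNPs whose joint p deteriorates, and uses the same deterministic
tie-breaks as pruning. Different published implementations of this
algebra differ in minor df and variance-update conventions; this package
fixes the convention above and validates it against brute-force
least squares on simulated individual-level data (agreement within 1 %
when the reference panel is the GWAS cohort itself), rather than against
any particular external binary.

A configurable |Δfreq| check (default 0.2) warns — and only warns — when
panel and GWAS allele frequencies disagree grossly.

## PWCoCo

Unconditional colocalization is evaluated first; PP.H4 ≥ 0.8 ends the
analysis (threshold configurable). Otherwise both traits undergo stepwise
selection; each of k ≥ 2 selected signals is isolated by conditioning on
the other k−1, and every combination of {unconditional + conditionals} ×
{unconditional + conditionals} except the already-evaluated unconditional
pair is colocalized — (k1+1)(k2+1) − 1 additional evaluations. The
reported evidence is the maximum PP.H4 over all evaluations.

**Single-signal regions.** The methodology's description of the k = 1
case can be read two ways: either the unconditional data already isolate
the lone signal (no conditional dataset needed), or the signal should
additionally be conditioned upon. The default here is the first reading —
conditioning a lone signal away removes the very association being
tested — but `single_signal_condition = TRUE` implements the second, so
neither interpretation is silently discarded.

## The synthetic-data generator

Haplotypes are drawn by thresholding a latent Gaussian AR(1) process
(correlation `ld_rho^|i−j|`) at per-SNP MAF quantiles; dosage is the sum
of two haplotypes. This produces a decaying-LD block whose induced
haplotype correlation is analytically computable (a tetrachoric-type
orthant probability, used as an oracle in the tests) without a coalescent
simulator. The exposure is linear-additive in standardized causal
dosages with noise scaled to approximately unit total variance; the
outcome is, depending on architecture, mediated through the exposure
score (`shared`, effect θ), driven by its own variant in the same LD
block (`distinct`), driven directly by one of two exposure signals
(`two_signal_one_shared` — the LD-masking regime PWCoCo exists for), or
pure noise (`null`). Binary outcomes threshold the liability at the case
fraction and report logistic score-test summary statistics (log-odds
scale); a linear-probability option exists because exact OLS oracles need
a closed-form model. Exposure cohort, outcome cohort and reference panel
are independent draws from named sub-streams of one master seed — the
two-sample MR assumption — and everything is byte-reproducible under that
seed.

Default desk-scale sizes are m = 200 SNPs, n_exposure = 5000,
n_outcome = 20000, n_ref = 2000. Real proteome GWAS are an order of
magnitude larger; effect sizes in the examples and tests are inflated
correspondingly (a standardized effect b gives |z| ≈ b√n) so the power
regimes of interest are reached at desk scale. The generator does **not**
model population structure, relatedness, imputation noise, allele-
frequency drift between cohorts, or genome-scale polygenicity — so a
green simulation-based test establishes the *statistical logic* of the
pipeline (calibration, discrimination, gating, recovery), not its
behavior under real-data pathologies such as stratification or
panel/GWAS ancestry mismatch.

## Numerical choices and degenerate inputs

- Two-locus EM for D′ starts at linkage equilibrium, stops at
  max |Δfreq| < 1e-8 or 1000 iterations; non-convergence raises a classed
  condition carrying the last estimate. D′ is defined as 0 when D ≈ 0 to
  avoid 0/0 at monomorphic-ish loci; constant dosage columns are a hard
  error for all LD computations.
- LD is genotypic (dosage correlation); whether published r²/D′ figures
  are haplotypic or genotypic is often unstated, and the genotypic
  convention matches what is computable from unphased reference panels.
- Missing dosages are mean-imputed per SNP — deterministic and standard.
- Joint fits reject condition numbers above 1e8 and negative residual
  variance (inconsistent summary data) with informative errors.
- All tie-breaks (pruning, stepwise selection) are total orders, making
  every run order-invariant and reproducible.

## Known limitations

Trans-pQTL instruments, Steiger filtering, MR-Egger/weighted-median
sensitivity estimators, SuSiE-based colocalization, >2-trait
colocalization, VCF/BGEN input and genome-wide LD storage are out of
scope. The F-statistic is not used for instrument pruning. Secondary
outcomes reuse the MR machinery only (no colocalization), reporting both
nominal and Bonferroni-adjusted flags because per-outcome multiplicity
handling is a reporting choice, not a modeling one.
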