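---
title: "Drug-target Mendelian randomization with metabolite mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with metabolite mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The design

`mrmediate` implements a two-sample Mendelian randomization (MR) analysis
for a drug target with mediation through circulating metabolites. The
motivating setting is genetically proxied inhibition of a drug target
(SGLT-2, encoded by *SLC5A2*): variants in the cis region of the gene
that also move the drug's pharmacodynamic biomarker (HbA1c) proxy the
effect of lifelong target inhibition. With such instruments the package
asks two questions:

1. Does genetically proxied inhibition causally affect a binary outcome
   (here, constipation risk), expressed as an odds ratio per one
   standard deviation of biomarker lowering?
2. How much of that effect runs through a circulating metabolite,
   quantified as a proportion mediated from a two-step MR decomposition?

MR rests on three assumptions: instruments are associated with the
exposure (relevance), independent of confounders (exchangeability), and
affect the outcome only through the exposure (exclusion restriction).
The estimator suite and sensitivity tests in this package exist to probe
the third assumption, which is the one summary data can partially check.

## The model

For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its effect
on the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its log-odds
effect on the outcome, harmonized to a common effect allele. The
per-variant ratio estimate is $\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
with first-order weight $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.

* **IVW** solves the weighted regression of outcome on exposure effects
  through the origin: $\hat b = \sum w'_j \hat\beta_{Xj}\hat\beta_{Yj} /
  \sum w'_j \hat\beta_{Xj}^2$ with $w'_j = 1/\sigma_{Yj}^2$. The default
  is a multiplicative random-effects model: the fixed-effects standard
  error is inflated by $\max(1, \sqrt{Q/(k-1)})$, where $Q$ is Cochran's
  heterogeneity statistic at $\hat b$, so the reported SE never shrinks
  below the fixed-effects value.
* **MR-Egger** adds an intercept to the same weighted regression after
  orienting all exposure effects positive; a nonzero intercept indicates
  directional pleiotropy. The intercept is tested against a
  $t_{k-2}$ distribution, the slope against a normal, both with the same
  multiplicative scale floor.
* **Weighted median** sorts the $\theta_j$ and interpolates the
  standardized midpoint cumulative weights at one half; it is consistent
  while valid instruments carry over half the weight. Its SE is a seeded
  parametric bootstrap (default 1000 replicates) resampling
  $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from their sampling
  distributions.
* **Mode estimators** (simple and weighted) place a Gaussian kernel over
  the $\theta_j$ with bandwidth $\varphi\, 0.9 \min(\mathrm{sd},
  \mathrm{IQR}/1.349)\,k^{-1/5}$ and take the density argmax over a
  512-point grid; the largest cluster of agreeing instruments drives the
  estimate. Bootstrap SEs as above.
* **MR-PRESSO** computes each variant's residual against the
  leave-one-out IVW slope and compares the weighted residual sum of
  squares to parametric simulations from the leave-one-out expectations;
  it yields a global heterogeneity p-value, Bonferroni-adjusted
  per-variant outlier p-values, and a distortion test for the change in
  estimate after outlier removal. All simulation p-values use the
  add-one estimator, so the smallest attainable p is $1/(n_{sim}+1)$.

Estimates are reported on both the log-odds and the odds scale with the
fixed 95% multiplier 1.96, matching the published table layout.

### Instrument construction

The drug-target instrument cascade is: variants within a closed
$\pm$250 kb window of the gene locus at $p < 10^{-3}$; a biomarker
association filter at $p < 10^{-4}$; a colocalization gate requiring
PP.H4 > 0.70 between the target-expression screen and the biomarker in
the region; greedy LD clumping at $r^2 = 0.8$ within 250 kb; and
per-variant F statistics $(\hat\beta/\sigma)^2$ with the strict $F > 10$
strength convention. All thresholds are strict `<` comparisons, windows
are closed intervals, and every filter is configurable — the metabolite
regime uses the same clumping code at $r^2 = 0.001$ within 10,000 kb,
with a genome-wide threshold $5\times10^{-8}$ and a suggestive fallback
$5\times10^{-7}$ whenever fewer than three instruments survive.

The colocalization gate enumerates single-causal-variant configurations
with approximate Bayes factors, per-variant log-ABF
$\tfrac12\log(\sigma^2/(\sigma^2+W)) + \tfrac12 z^2 W/(\sigma^2+W)$,
priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, and prior effect
variances $0.15^2$ (quantitative) or $0.2^2$ (binary). The method
assumes at most one causal variant per trait per region; feeding it a
region with several independent signals makes the H3/H4 split depend on
which signal dominates, which is why the synthetic pipeline exercises
the gate on single-signal regional fixtures and treats the gate as
optional when no biomarker cohort is supplied.

### Multivariable MR by model averaging

When several correlated metabolites survive screening, subsets of
factors are scored on the inverse-variance-weighted scale by a conjugate
normal prior on coefficients (prior SD 0.5) with the residual variance
profiled out, and an independent-inclusion model prior (probability 0.1
per factor). The marginal inclusion probability (MIP) of a factor is the
summed posterior of all models containing it; its model-averaged causal
effect (MACE) is the posterior-weighted mean of its conditional
posterior-mean coefficients. The empty model is part of the enumeration:
with null data every MIP then falls back to its prior, which is the
behavior that makes MIPs interpretable. Enumeration is exhaustive and
deliberately capped at 15 factors; the intended use is after a
metabolite-wide screen that leaves a small candidate set. Permutation
p-values jointly permute the outcome rows and report add-one exceedance
fractions of the MIPs.

### Two-step mediation

With $\beta_1$ the exposure-to-metabolite effect, $\beta_2$ the
metabolite-to-outcome effect (both from univariable MR with their own
instruments), and $T$ the total exposure-outcome effect, the indirect
effect is $\beta_1\beta_2$, the proportion mediated is
$\beta_1\beta_2/T$ (signed; shown as a percent to two decimals), and the
direct effect is reported as $T - \beta_1\beta_2$. The denominator is
the total effect, and the direct effect is derived by subtraction rather
than re-estimated by multivariable MR — with one mediator the two
presentations are algebraically linked, and the subtraction form follows
directly from the product-of-coefficients definition. A delta-method SE
for the indirect effect, $\sqrt{\beta_2^2 v_1 + \beta_1^2 v_2}$, is
computed when the path variances are available; it is labelled an
extension because summary-data two-step MR does not usually provide an
interval for the proportion.

## Harmonization choices

Matching across cohorts is purely identifier-driven; positions are
carried for window filters only. Allele alignment handles swapped
alleles (sign flip, frequency reflection) and strand complements.
Palindromic variants (A/T, C/G) cannot be resolved from allele letters:
the default policy `infer_by_eaf` aligns them by matching minor alleles
when both frequencies are outside $0.5 \pm 0.08$ and drops them as
ambiguous otherwise; a strict `drop` policy is available. Every excluded
variant lands in a drop log with a reason — nothing is silent. After
harmonization, `orientToInhibition()` jointly sign-flips each variant's
effect tuple so all exposure effects are nonnegative; ratio estimators
are invariant to this flip, so it only fixes the reporting scale
("per SD of biomarker lowering").

Missing effect-allele frequencies are tolerated at read time but force
palindromic variants into the drop path, since frequency inference is
then impossible.

## What the generator emulates

`simulateMediationGwas()` draws three (optionally four) cohorts of
summary statistics under the structural model
$M = \beta_1 X$, $Y = \theta X + \beta_2 M$ at per-variant level, with
standard errors $1/\sqrt{2 n \cdot \mathrm{maf}(1-\mathrm{maf})}$ driven
by the cohort sizes. Defaults are the package's reference study
conditions, chosen once:

* 14 exposure instruments in a cis block on chromosome 16, cohort sizes
  344,182 (exposure), 7,821 (metabolite) and 218,792 (outcome);
* true effect draws $\gamma_j \sim N(0, 0.03^2)$ conditioned on
  instrument-grade strength $|\gamma_j|/\sigma_{Xj} > 6$, giving F
  statistics in the tens to hundreds as biobank-scale glycemic hits
  show, and a mediator-path z around 3 at the metabolite sample size;
* structural coefficients $\beta_1 = 0.5$, $\beta_2 = 0.3$,
  $\theta = 0.45$, i.e. a total effect of 0.60 and a true proportion
  mediated of exactly 0.25;
* 10 mediator instruments on chromosome 1 (the metabolite's own
  genome-wide hits, strength-conditioned at the metabolite sample size)
  that affect the outcome only through the metabolite — these identify
  $\beta_2$, exactly as the metabolite GWAS hits do in the real design;
* optional pleiotropy ($\alpha$ terms on the mediator and outcome),
  planted outcome outliers in units of the outcome SE, and an optional
  independent biomarker replicate of the exposure GWAS for the
  colocalization gate.

The binary outcome is approximated on the log-odds scale with Gaussian
summary-statistic sampling, the standard two-sample MR simulation
practice. Features of real data deliberately not emulated: genome-wide
LD between instruments (instruments are simulated independent; the LD
matrix is identity), winner's curse from discovery-based selection
(replaced by the strength conditioning), sample overlap between cohorts,
and case-control ascertainment effects. Passing tests therefore show
that the estimators and the pipeline recover a known truth under clean
two-sample assumptions — not that any particular real dataset satisfies
those assumptions.

The colocalization fixture `simulateColocRegion()` builds an AR(1) LD
region ($r_{ij} = \rho^{|i-j|}$, default $\rho = 0.9$, 200 variants)
with one shared or two separated causal variants and draws the noise
correlated by the LD matrix within each trait. That correlation is the
joint sampling distribution of marginal GWAS estimates under LD;
independent noise would let different neighboring variants top the two
traits and misclassify shared-causal regions as distinct.

## Numerical choices

* P-values are floored at $10^{-300}$ so the $(0,1]$ invariant survives
  extreme z scores.
* Coloc and model-averaging evidence is accumulated in log space
  (log-sum-exp); the H3 term uses `log1p` against catastrophic
  cancellation.
* The model-averaging marginal likelihood floors the profiled residual
  sum of squares at $10^{-300}$: an exactly fitting (or all-zero)
  outcome would otherwise send every model's likelihood to infinity;
  with the common floor, tied models fall back to their priors.
* Degenerate mode bandwidths (all ratios identical) return the common
  ratio; a zero IQR with positive SD falls back to the SD.
* Clumping treats LD pairs missing from the matrix as $r^2 = 1$ inside
  the window (conservative removal) and logs them; p-value ties break by
  identifier for determinism.
* Bootstrap and simulation routines take a mandatory seed and restore
  the caller's RNG state; the generator produces bitwise-identical
  output for identical configurations.

## Problem sizes in the checks

The test suite validates the calibration claims at these sizes, chosen
to make the Monte-Carlo error small relative to each asserted tolerance:
IVW calibration and Egger size on 1,000 replicates each; median
robustness on 500 replicates of 15 instruments with 40% contaminated by
a 25-outcome-SE directional shift (strong contamination, where the
median's breakdown advantage is the property of interest); MR-PRESSO
detection on 200 replicates with a planted 10-SE outlier plus 500 null
replicates for uniformity; colocalization on 100 shared and 100 distinct
regions; model-averaging ranking on 200 replicates; oracle equivalence
(clumping, BH, weighted least squares, weighted median) on 1,000 random
instances; and end-to-end recovery of the 0.25 proportion mediated on
500 replicates. `scripts/acceptance.R` recomputes the same quantities
from scratch at the same sizes.

## Known limitations

* Correlated instruments are out of scope: IVW and friends assume
  independent variants, and the generator honors that. Use external
  clumping for real data with residual LD.
* The proportion mediated inherits the ratio-of-estimates instability
  when the total effect is small; the package refuses a zero total and
  reports the proportion signed rather than truncated to $[0,1]$.
* The distortion test reports a p-value but is not used as a gate,
  since the outlier-corrected estimate is always reported alongside the
  raw one.
* Exhaustive model enumeration caps at 15 factors; larger candidate
  sets need a pre-screen.
* The published mediation proportion of 22.76% is not exactly
  reproducible from the printed rounded path estimates (they give
  22.4%); the package documents both numbers and does not guess the
  unrounded internals.
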