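---
title: "Discriminating the botanical origin of Codonopsis Radix from untargeted metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating the botanical origin of Codonopsis Radix from untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crorigin)
```

## The problem

Codonopsis Radix (Dangshen) is traded from three botanical origins —
*Codonopsis pilosula* (CP), *C. pilosula* var. *modesta* (CM) and
*C. tangshen* (CT) — that are morphologically near-indistinguishable once
the roots are sliced, yet differ in metabolite content and market value.
`crorigin` implements a complete origin-authentication pipeline for
untargeted LC-MS feature tables of such material: compound annotation by
accurate mass, differential-metabolite screening, a rapid peak-area *ratio
method*, and a neural-network classifier, with the two classification
routes cross-validating each other.

This vignette records the methodological choices, their rationale, and what
the shipped tests do and do not demonstrate.

## Adduct mass arithmetic

Annotation rests on the calculated m/z of electrospray adduct ions,

$$ m/z \;=\; k\,M + \delta, $$

where $M$ is the monoisotopic mass of the neutral molecule (or intrinsic
cation), $k$ the molecular multiplicity (2 only for the deprotonated dimer
$[2M-H]^-$) and $\delta$ an electron-corrected mass delta:
protonation/deprotonation adds/removes a bare proton (1.0072765 Da),
$[M+Na]^+$ adds sodium minus one electron, the formate adduct
$[M+COOH]^-$ adds the CHO$_2$ anion *including* its extra electron, and the
intrinsic quaternary-nitrogen cations observed as $[M]^+$ subtract one
electron mass. This is the unique bookkeeping under which all 56 calculated
m/z values of the shipped reference table (`cr_compounds()`) reproduce to
four decimals, and it is asserted wholesale in the test suite.

Peak-to-database matching uses $|\mathrm{ppm}| \le 10$ and
$|\Delta RT| \le 0.20$ min by default — the processing tolerances of the
original acquisition software — and resolves ambiguity deterministically
(lowest $|\mathrm{ppm}|$, then $|\Delta RT|$, then record id) so that
annotation output is byte-stable. One published inconsistency is worth
noting: the reference table's printed error column does not agree with the
ppm error recomputed from its own rounded detected/calculated masses (the
published workflow evidently used unrounded detected masses). `crorigin`
reports ppm from its actual inputs and makes no attempt to reproduce that
column.

## The synthetic cohort

No raw data are deposited for this material, so the package ships a
generator (`synthetic_config()`, `generate_cohort()`) whose defaults *are*
the study conditions: 13 CP, 16 CM and 9 CT batches, three technical
replicates each (114 samples), 56 metabolites of which 29 are planted as
differential, plus 25 pooled-QC runs. Peak areas are log-normal,
$2^{\mathcal N(\mu_{mg},\sigma_m)}$, because areas are positive and noise
multiplicative; the default within-group log2 SD of 0.216 corresponds to a
~15% CV, consistent with pooled-QC repeatability in the single-digit RSD
range. Batches are the sampling unit: replicates share a batch-level latent
mean and add only small replicate noise (log2 SD 0.05), mirroring parallel
processing of the same material.

The planted structure encodes the qualitative findings the analysis must
recover:

* a **reference metabolite** (3′-hydroxy codonopyrrolidium B) flat across
  groups with the smallest SD of all metabolites (log2 SD 0.02);
* four **ratio markers** placed relative to the reference so that every
  sample's marker/reference area ratio satisfies its documented decision
  interval, with mean-level margins of at least 25% (validated at
  construction; violating draws are redrawn, at most 100 times per batch);
* the remaining differential metabolites cycle through three effect
  patterns (CT up 4-fold, CT down 4-fold, or a CP/CM split), all well
  beyond the 2-fold screening gate;
* null metabolites are flat across groups (pairwise mean ratios < 1.3), and
  sit in a tight high-abundance band so the 75th-percentile normalization
  factor is an order statistic of origin-invariant compounds — without
  this, percentile normalization itself injects group-structured
  common-mode noise that can exceed the reference compound's own
  variability.

One deliberate difference from the study's bookkeeping: the published
analysis counts the reference compound among the 29 differential
metabolites while also describing its content as stable across groups.
Those two properties are incompatible in a generative model (a stable
compound cannot clear a 2-fold fold-change gate), so the generator plants
the reference as a stable *non-differential* metabolite and
`select_reference()` searches all metabolites. The screen still recovers
exactly 29 differential metabolites and the workflow still selects the
planted reference.

What passing tests on this cohort show is parameter recovery under the
model's own assumptions — planted effects, log-normal noise, no
retention-time drift, no batch trends, no missing values beyond exact
zeros. They do not certify performance on real instrument data, where peak
picking, alignment and matrix effects add failure modes the generator does
not emulate.

## Preprocessing and screening

`percentile_normalize()` divides each sample by its own 75th-percentile
intensity (linear-interpolation quantile) and restores scale by the cohort
median of those percentiles — the standard percentile-shift normalization
of metabolomics processing software, and the only reading that is
scale-equivariant. `frequency_filter()` keeps a metabolite present (area
> 0) in at least 25% of the samples of at least one origin.
`log_transform()` uses `log2(area + floor)` with floor 0 when every area is
positive (making the transform exact) and half the smallest positive area
otherwise.

`anova_screen()` runs a classical one-way fixed-effects ANOVA per
metabolite on log2 areas and computes fold changes on the *linear*
normalized group means against the central group (CT), passing a metabolite
when `p < 0.05` and any group-vs-CT fold change (or its reciprocal) is at
least 2. Raw p-values are the default, matching the original workflow's
convention; Benjamini–Hochberg adjustment is available behind
`screen_config(adjust = "BH")`. The p-values are cross-checked against a
label-permutation test in the suite. Heat-map clustering (`hca()`) uses
z-scored log areas, Euclidean distance and Ward linkage — the de-facto
metabolomics default; the original report names no algorithm — and the
k = 3 sample partition on the default cohort is pure by origin.

## The ratio cascade

The rapid method normalizes four marker areas by the reference compound
within each sample (making the decision scale-free) and applies strict
decision intervals with mutual confirmation:

| stage | ratio | CT side | non-CT side |
|---|---|---|---|
| 1 | codonopyrrolidium A / ref | > 4.5 | < 1.2 |
| 1 | codonopyrrolidium D / ref | < 0.21 | > 0.45 |

| stage | ratio | CP side | CM side |
|---|---|---|---|
| 2 | tryptophan / ref | > 0.17 | < 0.14 |
| 2 | codonopsinol A / ref | > 0.15 | < 0.13 |

Both stage-1 votes must say CT for a CT call; both must say non-CT to
proceed to stage 2, where the two votes must again agree. The published
protocol does not say what happens inside the unclaimed gaps (e.g. an
A-ratio of 2) or when the two rules disagree; since its whole point is
mutual confirmation, `classify_ratios()` surfaces non-confirmation as
`INDETERMINATE` or `CONFLICT` rather than guessing. Boundary values fall in
the gap (strict inequalities, matching the "more than"/"below" wording).

## Chemometric models

All models consume the screened metabolites' log2 normalized areas.

**PCA** is mean-centered SVD. **PLS-DA** is NIPALS PLS2 on centered X and
the centered one-hot class matrix, reporting `R2Y`, leave-one-out `Q2Y`
(`1 - PRESS/SSY`) and VIP scores (whose squares average 1 by
construction); the implementation is cross-checked against
`mixOmics::plsda` in the suite, and the characteristic overfitting
signature — `Q2Y` falling from 2 to 3 components while `R2Y` rises — is
reproduced on the cohort with appended noise features. **LDA** is
shared-covariance Gaussian LDA via `MASS::lda`, confidence = maximum
posterior.

The **neural network** is the package's own implementation of the
era-classic 3-layer momentum backprop: logistic sigmoid units, squared
error against one-hot targets, learning rate 0.7, momentum 0.3, exactly
100 iterations, weights initialized uniform(−0.5, 0.5) from a seed,
features z-scored with training-set statistics. Updates are applied *per
pattern* in fixed sample order. A full-batch variant was evaluated and
rejected: at these hyperparameters the summed-gradient step oscillates
without converging, and a mean-scaled batch step converges but does not
saturate the outputs within 100 iterations; per-pattern updates — the
default in the classic implementations this emulates — reach complete
separation with near-unit confidence inside the stated budget. The hidden
width is not stated in the source description ("3 layers" only); the
default of 10 units is config-exposed, and any width ≥ 5 separates the
synthetic cohort. Prediction confidence is the maximum sum-normalized
sigmoid output — a bounded, cross-model-comparable reading of "strength of
assignment"; the confidence measure of the original software is
undocumented.

Validation follows the study design: leave-one-out cross-validation for
model comparison (standardization recomputed inside each fold, so nothing
leaks from the held-out sample), then retraining on a stratified
two-thirds split with external validation on the held-out third.
The split assigns whole batches (9/4 CP, 11/5 CM, 6/3 CT), never dividing
technical replicates across the split — an exact per-class 2/3 at batch
level is non-integral, and this rounding reproduces the published 78/36
sample totals while preventing replicate leakage. Finally
`cross_method_agreement()` tabulates the ratio calls against the network's
predictions; on the default cohort the two methods agree on every decided
sample.

## Numerical choices and problem sizes

* Quantiles: linear interpolation (R type 7), fixed for reproducibility.
* Display rounding of m/z: half-even to 4 decimals; all comparisons on
  unrounded values.
* NIPALS inner loop: relative tolerance 1e-8 on the score vector, at most
  500 iterations, then an error; degenerate (rank-exhausted) components
  truncate the model.
* Ties: annotation (ppm, then RT, then id), reference selection (lowest
  column index), argmax label (first class in sorted order).
* All stochastic routines take explicit seeds; the default is 20260218.
* The shipped tests and the acceptance script run the full 114-sample
  cohort; the multivariate-model property tests use 38 batch-mean profiles,
  the package's choice of a compact yet realistic problem size.

## Limitations

The generator does not emulate retention-time drift, inter-batch
instrument trends, censored (missing-not-at-random) low-abundance
features, or correlated metabolite blocks; conclusions about those failure
modes cannot be drawn from this package's tests. The decision thresholds of
the ratio cascade are fixed constants taken from the source material —
applying them to other instruments or extraction protocols requires
re-deriving the intervals. PCA/PLS-DA on real cohorts of this size are
prone to overfitting (which is precisely why the network and the ratio
method carry the classification here); `Q2Y` should always be inspected
before trusting a PLS-DA separation.
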