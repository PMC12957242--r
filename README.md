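# crorigin

Origin discrimination of Codonopsis Radix (Dangshen) from untargeted
LC-MS metabolomics feature tables.

Codonopsis Radix is traded from three botanical origins — *Codonopsis
pilosula* (CP), *C. pilosula* var. *modesta* (CM) and *C. tangshen* (CT) —
that are hard to tell apart once the roots are processed, yet differ in
metabolite content, efficacy and price. `crorigin` is aimed at analysts
authenticating such multi-origin herbal material from high-resolution
mass-spectrometry data. It provides:

* **Adduct mass arithmetic and annotation** — molecular-formula parsing,
  monoisotopic masses, electron-corrected ESI adduct m/z
  (`[M+H]+`, `[M−H]−`, `[M+Na]+`, `[M+COOH]−`, `[2M−H]−`, and `[M]+` for
  intrinsic quaternary-nitrogen cations), ppm errors, neutral-loss
  annotation, and deterministic peak-to-database matching at 10 ppm /
  0.20 min. A 56-compound Codonopsis reference database ships with the
  package (`cr_compounds()`).
* **A synthetic cohort generator** emulating the 38-batch study design
  (13 CP / 16 CM / 9 CT batches × 3 technical replicates, 56 metabolites
  with 29 planted differentials, a low-variance reference compound,
  pooled QC runs), so the whole pipeline is testable without raw data.
* **Preprocessing** — 75th-percentile normalization, 25% frequency
  filtering, log2 transform, QC repeatability metrics (RSD, ppm).
* **Differential screening** — per-metabolite one-way ANOVA on log2 areas
  with linear fold changes against the central group (pass: p < 0.05 and
  FC ≥ 2), reference-metabolite selection, Ward/Euclidean heat-map
  clustering.
* **The ratio method** — a two-stage cascade on four marker/reference
  peak-area ratios: codonopyrrolidium A (CT > 4.5, others < 1.2) and
  codonopyrrolidium D (CT < 0.21, others > 0.45) mutually confirm a CT
  call; tryptophan (CP > 0.17, CM < 0.14) and codonopsinol A (CP > 0.15,
  CM < 0.13) then separate CP from CM. Non-confirmation is surfaced as
  INDETERMINATE or CONFLICT, never guessed over.
* **Chemometrics** — PCA, NIPALS PLS-DA with R2Y / leave-one-out Q2Y /
  VIP, LDA, and a 3-layer momentum-backprop neural network (learning rate
  0.7, momentum 0.3, 100 iterations) with sum-normalized confidence
  scores, leave-one-out cross-validation, input-weight feature ranking,
  and a stratified 2/3–1/3 batch-level external-validation protocol.

The core quantity behind annotation is `m/z = k·M + δ`, with `M` the
monoisotopic formula mass and `δ` an electron-corrected adduct delta
(e.g. +1.0072765 Da for protonation, +22.9892207 for `[M+Na]+`,
+44.9982028 for formate); the ratio method classifies each sample from
`area(marker) / area(reference)` against fixed decision intervals; the
network reports `confidence = max_k ŷ_k / Σ_k ŷ_k` over its sigmoid
outputs.

## Worked example

Annotate a few peaks against the shipped compound database:

```r
library(crorigin)
db <- cr_compounds()
peaks <- data.frame(mz = c(115.0045, 419.1665, 350.1971),
                    rt_min = c(0.80, 15.89, 11.07))
match_peaks(peaks, db)
#>         mz rt_min id                name calculated_mz error_ppm delta_rt
#> 1 115.0045   0.80  1         Maleic acid      115.0037  7.111472    0.004
#> 2 419.1665  15.89 43          Lobetyolin      419.1676 -2.716230    0.002
#> 3 350.1971  11.07 35 Codonopyrrolidium A      350.1962  2.571642   -0.001
```

Each peak lands on its accurate-mass match; `error_ppm` is the relative
mass deviation in parts per million, well inside the 10 ppm tolerance.

Run the full study on the default synthetic cohort:

```r
report <- run_study(study_config())
report
#> <study_report>
#>  screened metabolites: 29 (reference: 3'-hydroxy codonopyrrolidium B)
#>  HCA purity (k=3): 1
#>  ratio method: 100% over 114 decided samples
#>   LOOCV NN: 100% (min conf 0.9839)
#>   LOOCV LDA: 100% (min conf 1)
#>   LOOCV PLSDA: 100% (min conf 0.5316)
#>  external validation: 100% (min conf 0.9819) on 36 samples
#>  ratio/NN agreement: 1
```

Reading the numbers: the ANOVA + fold-change screen flags 29 differential
metabolites and picks 3′-hydroxy codonopyrrolidium B as the stable
reference; hierarchical clustering at k = 3 separates the cohort purely by
origin; the ratio cascade decides all 114 samples correctly; the neural
network classifies every sample in leave-one-out cross-validation and,
after retraining on a 78-sample batch-stratified split, classifies all 36
held-out samples with per-sample confidence ≥ 0.98; the two classification
routes agree on every decided sample.

## Package layout

* `R/` — implementation; `tests/testthat/` — unit, property and
  end-to-end acceptance tests; `inst/extdata/cr_compounds.csv` — the
  reference compound table; `vignettes/` — the methods vignette
  describing the models, their assumptions and limitations.
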