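---
title: "Methods: reporter-screen QC, hit calling, and ddCt quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter-screen QC, hit calling, and ddCt quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seapscreen)
```

seapscreen analyses plate-based reporter-gene compound screens of the kind
used to find transcription-modulating compounds in inflammation models: a
secreted reporter (SEAP) read out as luminescence (RLU) from 384-well
plates carrying background (M0), solvent (M1_DMSO) and positive (M1_TSA)
control wells plus one well per library compound, screened in two reads,
followed by qPCR confirmation of candidate compounds. This vignette is the
package's account of the statistical model behind each stage, the
parameters that matter, and the choices made where the design was open.

## Assay characterisation

Variability is summarised by the coefficient of variation,
`CV = 100 * SD / mean`, computed over technical replicates of one sample
(intra-assay) or over per-experiment means (inter-assay). The screening
window is summarised by the Z'-factor,

$$Z' = 1 - \frac{3\,(\sigma_{s} + \sigma_{n})}{|\mu_{s} - \mu_{n}|},$$

between a positive sample and a negative control; `Z' >= 0.5` is the
conventional "excellent assay" band, and values at or below zero indicate
overlapping distributions. Everywhere the *sample* (n − 1) standard
deviation is used: replicate counts in this setting are small (typically
n = 3), where the distinction is material, and the population form has no
advantage. Both statistics inherit the invariances the formulas imply —
CV is scale-invariant, Z' is invariant under common affine maps with
positive slope — and the test suite checks both properties directly.

Dilution linearity is assessed by ordinary least squares of
`log10(mean RLU)` on `log10(1/dilution factor)`. Regressing on the
concentration surrogate rather than the dilution factor makes the ideal
slope +1, which reads more naturally as "signal tracks concentration".
Levels whose mean is indistinguishable from background — mean at or below
the negative-control mean plus two negative-control SDs — are excluded
from the fit and flagged, because deep-dilution levels sit at background
and would otherwise flatten the fit; the two-SD margin is the usual
limit-of-detection convention. At least three usable levels are required;
fewer is reported as an error rather than a two-point "fit".

## Hit calling

The hit rule is deliberately simple and local. For every plate and every
read separately, the mean `m` and sample SD of the **solvent-control
(M1_DMSO) wells only** define an activation threshold `m + k * SD` with
`k = 3` by default. A compound is a hit iff its signal *strictly* exceeds
the threshold in **every** read (the dual-read AND rule). Strictness at
the boundary is a deliberate tie-break: "more than k SDs" means more
than, and a signal exactly at the threshold is not called. M0 and M1_TSA
wells are quality references only — the positive control sits far above
the threshold by design and would inflate the SD if pooled.

Consequences of this construction, each covered by a property test:
the hit set shrinks monotonically as `k` grows; calls on one plate are
unaffected by any change on another plate; and the dual-read hit set is
exactly the intersection of the per-read exceedance sets. Thresholding is
done on raw RLU, with no log transform or plate normalisation, matching
how such screens are conventionally gated; a log-scale variant was
considered and rejected as a default because the rule's published form is
additive in SD units.

Inhibitor-side calling (`signal < m - k*SD`) is implemented but warns
when requested: in the high-CV regime this package targets (control CVs
of 25–50%), `m - 3*SD` sits near or below zero RLU and the rule has
little power against inhibitors — the same asymmetry that motivates
activator-only selection in practice.

The viability counterscreen (an ATP-luminescence read taken during read
2) guards against cytotoxic artefacts. Relative viability is the
compound well's viability over the plate's solvent-control viability
mean. Below the cutoff (default 0.7 — no published convention exists, so
the value is configurable and recorded in output metadata) a compound is
flagged `reduced_viability`; if its reporter signal is additionally below
the solvent-control mean it is flagged `viability_confounded`, the
signature of a compound whose apparent signal change is just cell death.
Activator hits with reduced viability keep hit status but carry the flag,
since a genuine activator can also be mildly cytotoxic.

## ddCt relative quantification

Technical Ct replicates are averaged per (experiment, condition, gene);
Ct values outside (0, 45] are rejected as outside any plausible cycler
range. `dCt = Ct_mean(gene) − Ct_mean(reference)` normalises to a
reference gene (default RPL37A), and fold change versus the calibrator
condition (default M0) is `2^−ddCt`.

One genuinely open convention is how to attach an SD to a fold change.
This package computes `2^−(dCt_r − mean dCt of the control group)` **per
biological replicate** `r` and reports the mean and sample SD of those
per-replicate folds. The alternative — exponentiating the group-mean ddCt
and propagating errors on the Ct scale — produces geometric-mean-like
summaries that do not match the "mean fold ± SD" format of typical
relative-quantification tables, so it is not used. Two exact laws pin the
implementation down and are tested: adding any constant to every Ct value
(reference included) leaves all folds unchanged, and subtracting one
cycle from the target gene in the test group exactly doubles every
per-replicate fold.

Fold-suppression ratios divide the vehicle condition's mean fold by the
compound condition's mean fold for the same gene: a ratio of 100 means
the compound suppressed the gene's induction 100-fold, a ratio below 1
means further activation. Ratios compose over a shared control
(`sr(a,b)·sr(b,c) = sr(a,c)`), which the tests verify. A bundled
reference table (`reference_fold_changes()`) carries published-style
mean ± SD fold changes for a BET/HDAC-inhibitor panel (I-BET151,
Ro 11-1464, SAHA, TSA) and serves as the worked-example input for these
ratios.

### Statistical comparison harness

Group comparisons of fold changes follow a decision tree: Shapiro–Wilk
normality per group at α = 0.05 (the convention "normally distributed
data" never names a test; Shapiro–Wilk is the standard small-sample
choice), then a median-centred Levene test at α = 0.05 for "equal SDs".
All-normal, equal SDs: plain unpaired t-test (2 groups) or ordinary
one-way ANOVA with Dunnett's comparison against control (>2 groups).
All-normal, unequal SDs: Welch t-test, or Welch's ANOVA with Dunnett
contrasts computed under a heteroscedasticity-consistent (HC3)
covariance — the closest well-founded analogue of an unequal-variance
Dunnett procedure. Any group non-normal: exact Wilcoxon (2 groups) or
Kruskal–Wallis with Dunn's post-hoc (>2). Dunn's z statistics use the
standard pooled-rank variance with tie correction, and its p-values are
Holm-adjusted within the reported family ("Dunn's correction" leaves the
adjustment variant open; Holm is uniformly valid and never worse than
Bonferroni). A group of constant values is treated as non-normal (the
Shapiro test is undefined there), and a comparison in which every value
is identical is degenerate: p = 1 with a warning, rather than an error,
so screens of many genes do not abort on one flat gene. Significance
bands are `* < 0.05`, `** < 0.005`, `*** < 0.001`, `**** < 0.0001`.
Normality assessment needs at least three values per group; smaller
groups are a refusal, not a guess.

## The synthetic-data generator

Every stage is testable without external data because the generator
emits truth-labelled datasets with the statistical structure the
analysis assumes.

**Screen model.** Well signal = (per-read scale) × (role multiplier) ×
(compound effect) × mean-one log-normal noise. Noise is multiplicative
and log-normal because RLU signals are positive with SDs that grow with
the mean; the noise term is normalised to mean one (`meanlog = −σ²/2`)
so configured role means are the true means of the simulated signals —
without that normalisation every mean would be inflated by `exp(σ²/2)`
(about 10% at CV 0.45) and moment-based checks would be biased. Reads
share the compound's true effect but draw noise independently; no
correlated plate- or well-level noise term is added by default, because
weak read-to-read correlation is precisely the regime the dual-read AND
rule is designed for. Defaults: seven plates (four of 320 and three of
258 compounds — a 2054-compound deck across two libraries), 16 M0 + 16
M1_DMSO + 8 M1_TSA wells per plate, one well per compound per plate, M1
activation 3× over M0, TSA 10× over M1, read-1 scale 0.5 (phenol-red
attenuation), control CVs 0.45 (read 1) and 0.30 (read 2), three planted
5× activators and four cytotoxic compounds (viability fraction 0.2,
signal fraction 0.3). In this regime per-plate Z' between M0 and
M1_DMSO is negative and control CVs fall in the 25–50% band — the
realistic, noisy end of cell-based screening, where the mean + 3·SD rule
still recovers strong activators.

**Ct model.** Per (experiment, condition), the reference gene's level is
its baseline Ct plus biological noise; a target gene's level is the
reference level plus the gene's baseline dCt minus log2 of the planted
fold, plus gene-level biological noise; technical replicates add
independent technical noise (SD `sigma_tech` cycles, default 0.2) on top.
Defaults use technical triplicates and three biological replicates —
standard qPCR practice. Because target levels are built on the realised
reference level, reference-level biological noise cancels exactly in
dCt, as it does in a well-run assay. At zero noise the ddCt pipeline
inverts the generator exactly, and the suite checks this to floating
point.

**What the generator does not emulate:** plate-position artefacts (edge
effects, gradients), correlated read-to-read noise, dose–response
structure, amplification-efficiency deviations from 2.0, and Ct
censoring at the cycle limit. Passing tests therefore demonstrate that
the estimators and rules are correct under the stated model, not that
real screens are free of spatial or efficiency artefacts — on real data
those remain the analyst's responsibility.

## Problem sizes and numerical notes

The test suite and the acceptance script run the hit-rule recovery study
on 200 simulated single-plate screens (16 solvent wells, 43 compounds,
3 planted 5× activators) against a 40,000-replicate direct Monte-Carlo
oracle, and the fold-recovery study on 500 simulated experiments with
planted folds spanning 0.1–1000; these sizes give binomial standard
errors of ~1–2% while keeping a full run around a minute. Under the
fold-recovery conditions (technical SD 0.2 cycles on both target and
reference wells, triplicates, three biological replicates), the
estimator's log2 error SD is analytically ≈0.13, which places roughly
88–90% of estimates within ±15% of truth — a property worth knowing
when choosing replicate counts: a fourth technical replicate, or
halving technical noise, is what moves recovery decisively past 90%.

All randomness flows from explicit seeds: generators take a seed in
their config and restore the caller's RNG state afterwards; the pipeline
derives stage sub-seeds deterministically from its master seed, so a run
is a pure function of its configuration.
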