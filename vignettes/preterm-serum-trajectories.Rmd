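---
title: "Classifying postnatal serum-proteome trajectories in preterm infants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying postnatal serum-proteome trajectories in preterm infants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preemietraj)
```

## The analysis model

`preemietraj` analyses label-free (LFQ) serum proteomics of preterm
infants sampled longitudinally at postnatal days 0, 3, 7, 14 and 28. The
pipeline makes three modelling commitments:

1. **Missingness in LFQ data is intensity-dependent (MNAR).** A protein
   group drops out of a run mostly because its abundance approaches the
   detection limit. This motivates both the completeness filter (a protein
   quantified in too few runs cannot be summarised reliably) and the
   downshifted-normal imputation, which places imputed values *below* the
   observed distribution rather than at its centre.
2. **Per-day medians are an adequate cohort summary.** All trajectory and
   deviation statistics are computed on the median log2 intensity across
   infants at each day. Medians are robust to the heavy per-subject
   variability of acute-phase serum proteins, at the cost of ignoring
   within-subject correlation; this is a cohort-level, not a mixed-model,
   analysis.
3. **A trajectory is a (shape, magnitude) pair.** Shape is scored by the
   squared Pearson correlation ("similarity score") of the median profile
   against a theoretical template; magnitude by the signed trapezoidal area
   of the baseline-normalised profile over postnatal days ("effect size").
   Splitting shape from magnitude lets proteins with the same temporal
   pattern but different amplitude be distinguished, and the squared
   correlation makes the score direction-blind so the *sign of the area*
   alone carries direction.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_unique_precursors` | 2 | precursors | single-precursor quantifications are unstable; boundary inclusive ("two or more") |
| `min_frac_per_timepoint` | 0.50 | fraction | every day must be quantifiable for a trajectory; inclusive |
| `min_frac_per_group` | 0.40 | fraction | cohort-wide identification floor; the only rule applied to adults, who have no timepoints |
| `downshift` | 1.8 | SDs | centre of the imputation distribution below the observed mean |
| `width` | 0.3 | SDs | spread of the imputation distribution |
| QC `threshold` | 30 | CV % | conventional reproducibility cutoff; strict (`CV < 30` passes) |
| `r2_min` | 0.5 | — | minimum similarity for a non-stable call; inclusive |
| `area_min` | 20 | log2 × days | on the 0–28 day axis this is a sustained change of ≈ 0.71 log2 units |
| `alpha`, `lfc_min` | 0.05, 1 | —, log2 | both strict (`p_adj < 0.05`, `|LFC| > 1`) |
| `cv_stable_max` | 30 | CV % | trends with `|ΔCV|` below it count as similar |
| `quantile_low/high` | 0.05 / 0.95 | — | empirical window of "normal" between-group LFCs |

## Design choices where the design was open

* **Completeness rule conjunction.** The filtering sentence ("at least 50%
  identification per time point and 40% per group") is read as *both*
  conditions for infants and the 40% rule alone for adults: adults have a
  single pooled "timepoint", so a per-timepoint rule cannot apply to them,
  and the conjunction is the strictest internally consistent reading. Both
  readings are expressible through `filter_config()`.
* **Area over days, not indices.** Printed effect sizes of magnitude ~100
  are impossible on a 0–4 index axis for realistic log2 changes (they
  would require ~26 log2 units of sustained change) but correspond to
  plausible ~4 log2-unit changes integrated over a 0–28 day axis. `x_axis
  = "index"` remains available.
* **A single linear-in-day shape template.** Because the similarity score
  is a squared correlation, one monotone ramp scores increasing and
  decreasing patterns alike; additional templates (e.g. a step, or the
  generator's saturating exponential) can be supplied and are scored by
  maximum with the argmax recorded in `best_shape`.
* **Zero-variance profiles score 0**, not `NA`, so constant proteins are
  always classified stable rather than propagating missing values.
* **CVs on the linear scale.** Both the QC CV and the longitudinal CV
  back-transform log2 values before computing 100·SD/mean: a CV of
  log-scale values is not scale-free, and 30% cutoffs in proteomics QC
  conventionally refer to linear intensities. `cv_scale = "log2"` is
  exposed for sensitivity analysis.
* **Imputation scope is per sample** (column-wise μ, σ), the convention of
  mainstream proteomics software for downshifted-normal imputation; a
  global scope is available.
* **The deviation window is an empirical quantile window.** The screen's
  description mixes "normal distribution" language with quantile notation
  (including an apparent `Q_0.5` typo for `Q_0.05`); linear-interpolation
  empirical quantiles at 0.05/0.95 are the default, a fitted-normal window
  the option.
* **"Median CV of a group"** is operationalised as the longitudinal CV of
  the group's per-day median profile — one CV per protein per group. A
  per-subject CV is impossible in this design (one sample per subject per
  day).
* **QC pass does not gate downstream analyses by default**
  (`qc_restrict = FALSE`): the CV screen validates the workflow, while the
  quantification funnel is governed by the completeness filter.
* **The moderated t-test is re-implemented, not delegated.** Hyperparameters
  (d₀, s₀²) come from moment matching of log residual variances through
  digamma/trigamma identities; the test suite checks agreement with the
  `limma` oracle to ~1e-10 on shared fixtures, and the `d₀ = 0` and
  `d₀ → ∞` limits analytically.

## Numerical conventions

* Trigamma inversion uses Newton iteration with relative tolerance 1e-8;
  when the spread of log variances is not above its sampling expectation,
  d₀ is capped at 1e6 ("effectively infinite prior").
* Quantile and median conventions are R type-7 (linear interpolation;
  midpoint for even counts).
* Integration is trapezoidal between observed days — the standard
  area-under-curve convention; classification ties at the thresholds are
  resolved inclusively for `r2_min`/`area_min` and strictly for the
  significance and QC rules, following the respective published wordings.
* Zero intensities on ingest are treated as missing (standard LFQ
  convention); double log2 transformation is blocked by a scale flag.
* One master seed derives fixed per-stage substreams, so pipeline runs are
  byte-identical under a fixed (config, seed) and adding a stage cannot
  perturb earlier stages' draws.

## What the synthetic cohort does — and does not — establish

`generator_config()` defaults state the emulated world: 67 infants (49
AGA / 18 SGA), per-day availability 31/65/56/49/27, 6 adults, 7 QC
injections, 900 proteins (150 increasing / 150 decreasing / 600 stable),
log2 baselines ~ N(20, 2), residual SD 0.3 log2, planted plateau delta 3
log2 (area 42, twice the classification threshold), a +1.5 log2 SGA shift
on 30 proteins, logistic detection with midpoint 16 / slope 0.8 (≈ 10%
cell-level missingness, concentrated in low-abundance proteins), precursor
counts 1 + Poisson(3) (≈ 5% of cells below the 2-precursor filter), QC
technical SD 0.15 log2, 250 infant-only and 4 adult-only proteins. These
were chosen once as realistic serum-DIA values; they are a stated world,
not tuning knobs.

The generator emulates: the sampling design and availability funnel,
planted trajectory shapes (linear or saturating), group-level shifts, MNAR
dropout, precursor-evidence filtering, QC pooling, and the qualitative
infant/adult presence structure. It does **not** emulate: within-subject
autocorrelation, clinical covariates (sepsis, BPD, ventilation),
shared-peptide protein-group artefacts, batch or acquisition drift, or
heavy-tailed biological outliers (CRP-like spikes beyond the saturating
shape). A green recovery test therefore establishes that the classifier
recovers planted cohort-level patterns under realistic noise and dropout —
not that it would be robust to subject-level confounding the generator
never produces.

One interaction worth knowing: planted *decreasing* proteins with low
baselines get censored by the MNAR mechanism at late days, fail the 50%
per-timepoint rule, and leave the analysis set. That is the completeness
filter doing its job, and it is why a default run classifies fewer
decreasing than increasing proteins even though the generator plants them
symmetrically.

## Known limitations

* Cohort-level medians cannot separate a population shift from a
  subpopulation of extreme responders.
* The moderated test is a two-group equal-variance contrast; no covariate
  adjustment, trend/robust variants, or multi-factor designs.
* The deviation screen's empirical window flags ~10% of proteins as level
  deviations *by construction*; it ranks deviation, it does not test it.
* With imputation on, downstream statistics mix observed and model-imputed
  values; the imputation mask is returned (and written) so any result can
  be audited against the fraction of imputed cells behind it.
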