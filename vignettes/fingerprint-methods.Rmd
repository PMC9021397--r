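---
title: "Serum NMR fingerprinting for survival risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum NMR fingerprinting for survival risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrisk)
```

## The problem

In chronic heart failure — here, dilated cardiomyopathy (DCM) — clinicians
stratify the risk of death with a small number of established markers:
left-ventricular ejection fraction (LVEF), NT-proBNP, NYHA functional
class. A serum ¹H-NMR spectrum offers a complementary view: a single
measurement captures dozens of metabolites and lipoprotein signals at once.
`nmrisk` implements a *fingerprinting* approach to this idea: the whole
binned spectrum, assigned and unassigned signals alike, is treated as one
multivariate pattern and fed to a supervised classifier whose output — a
per-patient metabolomic risk class — is then evaluated as a survival
predictor and combined with the clinical markers.

The package covers the full chain: spectral preprocessing, the classifier,
survival analysis, rule-based risk combination, univariate feature
statistics, and a synthetic-cohort generator that stands in for patient
data so every stage is testable end to end.

## Spectral preprocessing

**Calibration.** `calibrate_ppm()` shifts the chemical-shift axis so the
tallest point inside a ±0.05 ppm window around the anomeric glucose signal
lands exactly at δ 5.24. This is an optional convenience for
frequency-domain spectra that are otherwise already phased and
baseline-corrected; time-domain processing is out of scope.

**Binning.** `bin_spectrum()` segments 0.2–10 ppm into 0.02 ppm bins (490
in total) and integrates each trapezoidally, which keeps the result exact
for linearly interpolated spectra on arbitrary monotone grids and makes
the integral independent of the axis direction. Residual water
(4.37–5.13 ppm) and ethanol (1.12–1.23, 3.53–3.73 ppm) regions are
removed. A bin is dropped iff its interval has positive-length overlap
with an exclusion interval — the conservative convention — which retains
**434** bins. Other defensible edge conventions retain 434–439; the count
under this package's convention is frozen in a regression test. Bins are
labeled by their starting ppm.

**Normalization.** `pqn_normalize()` applies probabilistic quotient
normalization: the reference is the element-wise median spectrum; each
sample's quotient is the median, over bins where the reference is strictly
positive, of its ratio to the reference, and the sample is divided by that
quotient. The quotient estimates the sample's overall dilution, so PQN is
tested by construction: spectra simulated with known dilution factors and
no other variance source must yield quotients correlating > 0.99 with the
applied dilutions. One subtlety: renormalizing an already-normalized
matrix is only an *exact* no-op if the second pass reuses the stored
reference, which is what the implementation does; recomputing a reference
from normalized data would give quotients near, but not identically, 1.

## The classifier

**PLS-DA.** `fit_pls()` is a NIPALS partial-least-squares regression of a
−1/+1 class code on the binned matrix, classifying by the sign of the
predicted score. Data are **mean-centered only**. Whether to autoscale is
a genuine design choice in fingerprint work; centering-only preserves the
intensity weighting of the spectrum (strong signals matter more), which is
the common default for NMR fingerprints, and it is what this package
fixes. Seven components are the package-wide default. The implementation
is cross-checked in the tests against an independent chemometrics library
and against a hand deflation on small matrices.

**Validation.** `loocv()` refits the model n times, each fold excluding
one sample, and scores only held-out predictions — the resubstitution
optimism of a 7-component model on a few hundred collinear bins is
substantial, and a property test asserts that LOOCV accuracy does not
exceed resubstitution accuracy on average.

**Balanced ensemble.** Cohorts like this one are imbalanced (roughly 3:1
survivors). `balanced_ensemble()` neutralizes the imbalance by resampling:
each of `n_iter = 100` iterations draws `per_class = 25` patients per
class without replacement, fits PLS-DA on the subsample, and votes. A
design question the method description leaves open is where
out-of-subsample patients get their votes. The resolution implemented
here: subsample members receive their held-out LOOCV prediction,
everybody else the fitted model's prediction, so every patient accrues
exactly `n_iter` votes — which is what a well-defined majority vote over
iterations requires. This is recorded as the package's choice, not
asserted as anyone else's intent.

**Majority vote and the gray zone.** `majority_vote()` assigns the class
with more votes; the margin is `|vote share − 0.5|`, and patients with a
margin strictly below 0.10 are flagged *gray-zone* (ambiguous). The margin
is computed from integer vote counts so a margin exactly at the threshold
is never misclassified by floating-point error. An exact 50/50 tie goes to
the survivor class — the clinically neutral, lower-risk default — and is
always flagged gray. Iteration k draws its subsample from its own seed
substream, so enlarging `n_iter` never reshuffles earlier iterations.

**VIP.** `vip_scores()` implements the standard variable importance in
projection, `VIP_j = sqrt(p · Σ_a SS_a w²_ja / Σ_a SS_a)` with
`SS_a = q²_a t'_a t_a`; by construction the mean squared VIP is exactly 1,
which doubles as a free correctness check, and variables with VIP > 1 are
flagged important.

## Survival analysis

`km_estimate()`, `logrank_test()`, `cox_fit()` and
`likelihood_ratio_test()` are implemented from the definitions — the
product-limit estimator; the observed-minus-expected statistic with
hypergeometric variance; Newton–Raphson maximization of the partial
likelihood with Breslow (default) or Efron tie handling, Wald 95% CIs on
the log-hazard scale, and likelihood-ratio p-values. The `survival`
package serves as the independent oracle in the tests (agreement to
≤ 1e-6 on simulated data for coefficients, ≤ 1e-10 for KM steps), never as
the implementation. Breslow is the default because it matches the simplest
published formula and makes the log-rank/score-test identity exact on
tie-free data, which is itself a property test. Transplant-style competing
events are treated as censoring; time-varying covariates and
proportionality diagnostics are out of scope.

Multivariate adjustment uses a fixed dichotomized covariate specification
(`clinical_covariates()`): male sex, age at diagnosis > 60 y, time from
diagnosis > 15 y, NT-proBNP > 400 pg/ml, LVEF class indicators (reference:
preserved), NYHA II and III–IV (reference: I), SBP > 130 mmHg,
EDDi > 30 mm/m², LAVi > 40 ml/m² — all cuts strict at the boundary.

## Risk scores

`lvef_classify()` implements the guideline LVEF classes (< 40 high risk,
40–49 intermediate, ≥ 50 low); `ntprobnp_classify()` uses a strict
400 pg/ml cutoff. `combine_met_lvef()` uses metabolomics as the first
screen and lets LVEF override it only where LVEF is most prognostic:
survivor-predicted patients with LVEF < 35 become high risk,
deceased-predicted patients with LVEF > 50 become low risk, both
boundaries strict; in between, metabolomics governs. The
metabolomics × NT-proBNP combination has no published rule, so
`combine_met_ntprobnp()` exposes named strategies (`either_high` default)
rather than guessing a specific one.

## Feature statistics

`wilcoxon_screen()` runs per-feature two-sided rank-sum tests (exact for
≤ 10 per group without ties, normal approximation with corrections
otherwise — delegated to `wilcox.test`) with Benjamini–Hochberg adjustment
across features. `tertile_cox()` cuts a feature at its type-7 1/3 and 2/3
quantiles (ties to the lower tertile, deterministic and order-preserving —
a rank-replacement invariance test pins this) and fits indicator
covariates for the 2nd and 3rd tertile. `winsorized_correlation()`
replaces each tail's `floor(0.1·n)` extremes by the nearest retained order
statistic before taking Pearson correlation, with a t-type p-value on
`n − 2·g − 2` degrees of freedom. `cohort_summary()` produces the usual
baseline table: median (MAD) and n (%) per vital-status group, Wilcoxon or
chi-square/Fisher (Fisher when any expected count < 5 — the choice of
categorical test is this package's, as clinical reports rarely state it)
and BH adjustment across rows. The MAD is scaled by 1.4826 by default
(common in clinical reporting; the raw MAD is a flag away — the two cannot
be distinguished from a published table and nothing downstream depends on
the choice).

## The synthetic cohort generator

`generate_cohort()`, `generate_spectrum()` and `generate_feature_table()`
emulate the statistical structure the analysis assumes:

* **Survival**: exponential per class — survivor-class hazard 0.02/yr by
  default, multiplied by a hazard ratio of 5.71 for the deceased class —
  with administrative censoring at 8 years. Exponential hazards were
  chosen because they admit closed-form checks (the empirical rate ratio
  of a large uncensored cohort must recover the configured hazard ratio,
  within 10% at n = 5000).
* **Covariates**: class-conditional normal (lognormal for NT-proBNP)
  distributions centered on the published baseline medians with
  MAD-derived spread, because only medians and MADs are published; the
  NT-proBNP/LVEF *joint* distribution of the deceased class is not, so no
  claim is made to reproduce published baseline p-values.
* **Spectra**: sums of Lorentzian multiplets (default linewidth
  0.004 ppm) at textbook chemical shifts for creatine, creatinine,
  trimethylamine-N-oxide, lactate, alanine, citrate, acetate, valine and
  glycine; broad (0.05 ppm) lipoprotein humps at 0.85 and 1.25 ppm; a weak
  very-broad macromolecular envelope so that, as in real serum, every bin
  carries some signal (this is what lets PQN estimate dilution from the
  whole spectrum); a glucose reference line at exactly 5.24 ppm; a
  per-sample lognormal dilution factor; and additive Gaussian noise. The
  informative class effects follow the expected biology — deceased-class
  means lower for creatine (×0.7) and higher for TMAO (×1.5), creatinine
  (×1.4) and lactate (×1.3); `effect_scale` raises all informative ratios
  to a power (0 = null cohort, ~2 for strongly separated benchmarks).
* **Reproducibility**: one master seed spawns per-patient substreams, so
  growing a cohort never reshuffles existing patients, and a fixed seed
  reproduces outputs byte-identically.

What the generator does **not** emulate: J-coupling fine structure, peak
position drift with pH, missing data, and any correlation between spectral
class and clinical covariates beyond their shared dependence on the latent
class. Passing tests on these cohorts therefore demonstrate correctness of
the machinery and calibration of its statistics under the stated model —
not clinical performance on real spectra.

## Numerical choices and problem sizes

* PLS deflation stops with an error if a component's weight or score norm
  falls below 1e-12 (rank exhaustion); requesting more components than
  `min(n − 1, p)` errors up front.
* Cox Newton–Raphson converges on relative log-likelihood change < 1e-9
  (cap 50 iterations, step-halving on decrease); |coef| > 15 triggers a
  monotone-likelihood (separation) warning.
* Test and acceptance simulations use cohorts of 106 (the motivating
  cohort's size and 80/26 class split) for ensemble benchmarks, n = 800
  with ~30% censoring for hazard-ratio recovery (the ~30% figure follows
  in closed form from baseline hazard 0.077/yr, a 50/50 class split at
  hazard ratio 5.71 and 8-year administrative censoring), n = 5000 for
  asymptotic checks, and 20-replicate permutation nulls. Because ensemble
  predictions within a cohort share fitted models, permutation accuracies
  are over-dispersed relative to iid binomial draws; calibration bands on
  mean permutation accuracy are therefore set at [0.40, 0.60].

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_patients = 106, prop_deceased = 26 / 106, seed = 1)
cohort <- generate_cohort(cfg)
spectra <- generate_spectra(cohort, cfg)
binned <- bin_spectra(lapply(spectra, calibrate_ppm))
normalized <- pqn_normalize(binned)

ens <- balanced_ensemble(normalized, cohort$true_class, seed = 1)
summary(ens)

risks <- risk_table(cohort, ens$votes$predicted_class)
cox_fit(as.numeric(risks$metabolomics == "high"),
        cohort$survival_time, cohort$event)
```

Or, as one call: `run_pipeline(pipeline_config(seed = 1))`, which writes
every stage artifact plus a JSON report.

## Known limitations

* The classifier is strictly two-class; no multi-class or orthogonal PLS.
* The number of PLS components is fixed by configuration, not selected by
  nested cross-validation.
* No peak alignment beyond global calibration; no deconvolution or
  metabolite quantification from spectra — a quantified feature table is
  consumed, never produced.
* The Cox implementation targets modest covariate counts (tens, not
  thousands) and has no penalization.
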