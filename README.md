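# nmrisk

Serum ¹H-NMR metabolomic fingerprinting for survival risk stratification in
heart failure.

In dilated cardiomyopathy, the risk of death is conventionally stratified
with left-ventricular ejection fraction (LVEF), NT-proBNP and NYHA class.
`nmrisk` implements the complementary *fingerprinting* route: the whole
binned serum NMR spectrum — assigned and unassigned signals alike — is
treated as one multivariate pattern, classified by a balanced-resampling
PLS-DA ensemble, and the resulting per-patient metabolomic risk class is
evaluated as a survival predictor, alone and combined with the clinical
markers.

For cohort spectra **X** (samples × 0.02-ppm bins, water/ethanol regions
excluded, PQN-normalized) and class code **y** ∈ {−1, +1} (+1 = deceased),
the core model is NIPALS PLS regression with mean centering only,

> t_a = E_{a−1} w_a, E_a = E_{a−1} − t_a p_aᵀ, ŷ(x) = (x − x̄)ᵀ B + ȳ,

classifying by sign(ŷ). Class imbalance is handled by drawing 25 patients
per class, 100 times; each draw contributes one vote per patient
(leave-one-out-validated for subsample members, model-predicted for the
rest), the majority vote assigns the class, and patients within 10
percentage points of a 50/50 split are flagged as a gray zone. Variable
importance uses the standard VIP formula (VIP > 1 ⇒ important). Survival
machinery — Kaplan–Meier, log-rank, Cox proportional hazards with
Breslow/Efron ties and likelihood-ratio tests — is implemented from the
partial likelihood, with the `survival` package used only as a test
oracle. Rule-based scores combine the metabolomic class with LVEF
(overrides at LVEF < 35% and > 50%) and NT-proBNP (> 400 pg/ml).

A synthetic-cohort module (Lorentzian peak spectra with class-dependent
creatine/TMAO/creatinine/lactate levels, per-sample dilution, clinical
covariates, exponential survival with administrative censoring) makes the
whole pipeline runnable and testable without any patient data.

## Worked example

```r
library(nmrisk)

cfg     <- sim_config(n_patients = 106, prop_deceased = 26/106, seed = 1)
cohort  <- generate_cohort(cfg)                   # 80 survivors, 26 deceased
spectra <- generate_spectra(cohort, cfg)
binned  <- bin_spectra(lapply(spectra, calibrate_ppm))
normed  <- pqn_normalize(binned)

print(normed)
#> <binned_matrix> 106 samples x 434 bins (width 0.02 ppm), pqn

ens <- balanced_ensemble(normed, cohort$true_class, seed = 1)
print(ens)
#> <plsda_ensemble> 100 iterations, 25 per class, 7 components
#>   3/106 samples in the gray zone (margin < 0.1)
#> TP 24  FP 1  TN 79  FN 2
#> sensitivity 0.923  specificity 0.988  accuracy 0.972

risks <- risk_table(cohort, ens$votes$predicted_class)
cox_fit(as.numeric(risks$metabolomics == "high"),
        cohort$survival_time, cohort$event)
#> <cox_fit> n = 106, events = 28, ties = breslow
#>      coef     HR CI95 lower CI95 upper
#> x1 1.3726 3.9456     1.8734     8.3096
#> LRT: chi-square 12.16 on 1 df, p = 0.000488
```

The ensemble recovers the latent spectral class of most patients (97.2%
accuracy here, with ambiguous ones flagged in the gray zone), and the
resulting metabolomic risk class separates survival (hazard ratio 3.9,
95% CI 1.9–8.3, for this synthetic cohort; the configured class hazard
ratio is 5.71 before censoring and misclassification dilute it). Your
numbers will match exactly at `seed = 1`. `run_pipeline(pipeline_config(seed = 1))` performs the same
chain end to end and writes per-stage CSVs plus a JSON report.

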