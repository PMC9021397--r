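#' Simulation configuration for a synthetic DCM heart-failure cohort
#'
#' Bundles the knobs of the synthetic cohort generator: cohort size and class
#' balance, the class-specific exponential survival model, administrative
#' censoring, per-sample dilution and spectral noise, and the master seed.
#'
#' The defaults emulate the study conditions the package targets: a cohort of
#' 106 dilated-cardiomyopathy patients of whom 26 die of heart-failure causes,
#' a between-class hazard ratio of 5.71, and follow-up truncated at 8 years.
#'
#' @param n_patients Number of patients.
#' @param prop_deceased Fraction of patients carrying the deceased
#'   (high-risk) spectral class; exactly `round(n_patients * prop_deceased)`
#'   patients are assigned to it.
#' @param hazard_ratio Instantaneous death-rate ratio, deceased class vs
#'   survivor class.
#' @param baseline_hazard Survivor-class hazard, events per year.
#' @param censor_time Administrative censoring time, years.
#' @param dilution_cv Between-sample coefficient of variation of the overall
#'   dilution factor applied to each spectrum (dimensionless).
#' @param noise_sd Standard deviation of additive Gaussian spectral noise
#'   (intensity units).
#' @param seed Master integer seed. Each patient draws from its own
#'   substream, so enlarging the cohort does not reshuffle existing patients.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_patients = 40, seed = 1)
#' cohort <- generate_cohort(cfg)
#' table(cohort$true_class)
#' @export
sim_config <- function(n_patients = 106,
                       prop_deceased = 26 / 106,
                       hazard_ratio = 5.71,
                       baseline_hazard = 0.02,
                       censor_time = 8,
                       dilution_cv = 0.15,
                       noise_sd = 0.002,
                       seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 4)
    stopf("invalid config: n_patients must be >= 4 (got %s)", n_patients)
  if (!is.numeric(prop_deceased) || prop_deceased <= 0 || prop_deceased >= 1)
    stopf("invalid config: prop_deceased must lie in (0, 1)")
  m <- round(n_patients * prop_deceased)
  if (m < 1 || m > n_patients - 1)
    stopf("invalid config: prop_deceased is degenerate for n_patients = %d",
          n_patients)
  if (hazard_ratio <= 0) stopf("invalid config: hazard_ratio must be > 0")
  if (baseline_hazard <= 0) stopf("invalid config: baseline_hazard must be > 0")
  if (censor_time <= 0) stopf("invalid config: censor_time must be > 0")
  if (dilution_cv < 0) stopf("invalid config: dilution_cv must be >= 0")
  if (noise_sd < 0) stopf("invalid config: noise_sd must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 prop_deceased = prop_deceased,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censor_time = censor_time,
                 dilution_cv = dilution_cv,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n_patients: %d (deceased class: %d)\n", x$n_patients,
              round(x$n_patients * x$prop_deceased)))
  cat(sprintf("  hazard: %.3g /yr (x %.3g for deceased class), censored at %g yr\n",
              x$baseline_hazard, x$hazard_ratio, x$censor_time))
  cat(sprintf("  dilution_cv: %g, noise_sd: %g, seed: %d\n",
              x$dilution_cv, x$noise_sd, x$seed))
  invisible(x)
}

# Class-conditional covariate distributions, centered on the published
# baseline table of the cohort this generator emulates (medians with MAD
# spread; NYHA class frequencies). Survivor class first, deceased second.
covariate_params <- function() {
  list(
    age_at_diagnosis = list(median = c(48.5, 55.5), mad = c(11.1, 17.0)),
    time_from_diagnosis = list(median = c(15, 15), mad = c(5.9, 7.4)),
    sbp = list(median = c(120, 110), mad = c(14.8, 14.8)),
    eddi = list(median = c(30.8, 36.9), mad = c(3.8, 5.7)),
    lavi = list(median = c(41.3, 47.8), mad = c(16.3, 26.9)),
    lvef = list(median = c(46.0, 37.5), mad = c(7.4, 9.6)),
    nt_probnp = list(median = c(180.6, 613.3), mad = c(176.0, 741.9)),
    p_male = c(0.688, 0.731),
    p_nyha = rbind(survivor = c(0.388, 0.512, 0.100, 0.000),
                   deceased = c(0.269, 0.462, 0.192, 0.077))
  )
}

# Quota assignment: patient i is deceased-class iff the running quota
# round(i * p) increments at i. Gives exactly round(n * p) deceased patients
# and is stable when the cohort grows.
assign_classes <- function(n, prop) {
  q <- round(seq_len(n) * prop)
  ifelse(q - c(0L, q[-n]) >= 1L, "deceased", "survivor")
}

#' Generate a synthetic heart-failure cohort table
#'
#' Draws per-patient clinical covariates from class-conditional distributions
#' (normal with MAD-derived spread for most variables; lognormal for
#' NT-proBNP) and survival times from class-specific exponential hazards with
#' administrative censoring at `config$censor_time`. `true_class` is the
#' latent spectral class used by [generate_spectra()] and
#' [generate_feature_table()]; the observed event indicator additionally
#' reflects censoring.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with one row per patient: `patient_id`,
#'   `true_class`, `survival_time` (years), `event` (1 = death), `lvef` (%),
#'   `nt_probnp` (pg/ml), `age_at_diagnosis` (years), `sex` (`"M"`/`"F"`),
#'   `nyha` (`"I"`..`"IV"`), `sbp` (mmHg), `eddi` (mm/m^2), `lavi` (ml/m^2),
#'   `time_from_diagnosis` (years), `dilution` (the latent dilution factor
#'   later applied to that patient's spectrum).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  cls <- assign_classes(n, config$prop_deceased)
  pars <- covariate_params()
  mad2sd <- 1 / stats::qnorm(0.75)  # MAD (scaled) ~ sd for a normal

  draw_one <- function(i) {
    k <- if (cls[i] == "deceased") 2L else 1L
    with_seed(derive_seed(config$seed, 1L, i), {
      rnorm_med <- function(p, lo = -Inf, hi = Inf) {
        v <- stats::rnorm(1, p$median[k], p$mad[k] * mad2sd)
        min(max(v, lo), hi)
      }
      lam <- config$baseline_hazard *
        if (k == 2L) config$hazard_ratio else 1
      t_death <- stats::rexp(1, lam)
      sdlog <- asinh(pars$nt_probnp$mad[k] / pars$nt_probnp$median[k]) /
        stats::qnorm(0.75)
      data.frame(
        patient_id = sprintf("P%03d", i),
        true_class = cls[i],
        survival_time = min(t_death, config$censor_time),
        event = as.integer(t_death <= config$censor_time),
        lvef = rnorm_med(pars$lvef, 5, 85),
        nt_probnp = stats::rlnorm(1, log(pars$nt_probnp$median[k]), sdlog),
        age_at_diagnosis = rnorm_med(pars$age_at_diagnosis, 18, 90),
        sex = if (stats::runif(1) < pars$p_male[k]) "M" else "F",
        nyha = sample(c("I", "II", "III", "IV"), 1,
                      prob = pars$p_nyha[k, ]),
        sbp = rnorm_med(pars$sbp, 70, 220),
        eddi = rnorm_med(pars$eddi, 15, 60),
        lavi = rnorm_med(pars$lavi, 10, 150),
        time_from_diagnosis = rnorm_med(pars$time_from_diagnosis, 0, 60),
        dilution = rlnorm_meancv(1, 1, config$dilution_cv),
        stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, lapply(seq_len(n), draw_one))
  rownames(out) <- NULL
  out
}

#' Default differential-effect map for synthetic quantified features
#'
#' Multiplicative concentration ratios (deceased-class mean over
#' survivor-class mean) for a panel of serum metabolites and
#' lipoprotein-related parameters. The informative directions follow the
#' biology the classifier is meant to pick up: deceased patients show lower
#' creatine and higher trimethylamine-N-oxide, creatinine and lactate; the
#' remaining panel members are null (ratio 1).
#'
#' @param n_null Number of additional null features appended to the named
#'   informative panel.
#' @return Named numeric vector of class effects.
#' @export
dcm_feature_effects <- function(n_null = 26) {
  eff <- c(creatine = 0.70, trimethylamine_N_oxide = 1.50,
           creatinine = 1.40, lactate = 1.30,
           alanine = 1.0, glucose = 1.0, citrate = 1.0, acetate = 1.0,
           valine = 1.0, glycine = 1.0)
  if (n_null > 0) {
    nul <- rep(1.0, n_null)
    names(nul) <- sprintf("lipoprotein_param_%02d", seq_len(n_null))
    eff <- c(eff, nul)
  }
  eff
}

#' Generate a synthetic quantified-feature table
#'
#' Emulates a targeted quantification panel (metabolite and lipoprotein
#' concentrations) for an existing cohort: lognormal concentrations with
#' between-subject coefficient of variation `cv`, with deceased-class means
#' multiplied by the per-feature class effect.
#'
#' @param cohort A cohort table from [generate_cohort()].
#' @param effects Named vector of multiplicative class effects
#'   (deceased / survivor); see [dcm_feature_effects()].
#' @param cv Between-subject coefficient of variation (>= 0).
#' @param seed Integer seed (per-patient substreams).
#' @return A `data.frame`: `patient_id` plus one numeric column per feature.
#' @export
generate_feature_table <- function(cohort, effects = dcm_feature_effects(),
                                   cv = 0.2, seed = 1L) {
  if (cv < 0) stopf("cv must be >= 0")
  if (anyDuplicated(names(effects)) || is.null(names(effects)))
    stopf("effects must be a uniquely named vector")
  p <- length(effects)
  vals <- t(vapply(seq_len(nrow(cohort)), function(i) {
    mult <- if (cohort$true_class[i] == "deceased") effects else rep(1, p)
    with_seed(derive_seed(seed, 3L, i), rlnorm_meancv(p, 1, cv) * mult)
  }, numeric(p)))
  colnames(vals) <- names(effects)
  cbind(data.frame(patient_id = cohort$patient_id, stringsAsFactors = FALSE),
        as.data.frame(vals))
}
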