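#' Pipeline configuration
#'
#' Validated bundle of every knob of an end-to-end run. Round-trips through
#' YAML via [read_pipeline_config()] / [write_pipeline_config()]; unknown
#' keys are rejected.
#'
#' @param input_mode `"synthetic"` (generate everything), `"spectra_dir"`
#'   (read TSV spectra + manifest from `input_path`), or `"binned_csv"`
#'   (read a pre-binned matrix from `input_path`).
#' @param input_path Directory or CSV for the non-synthetic modes; for
#'   `"spectra_dir"` a cohort CSV is expected at `cohort_path`.
#' @param cohort_path Cohort CSV for non-synthetic modes.
#' @param n_patients,prop_deceased,hazard_ratio,baseline_hazard,censor_time,dilution_cv,noise_sd
#'   Synthetic-cohort parameters, see [sim_config()].
#' @param effect_scale Class-separation exponent for the synthetic peak
#'   library ([dcm_peak_library()]).
#' @param bin_width,bin_range Spectral binning parameters (ppm).
#' @param calibrate Calibrate each spectrum to the glucose doublet first?
#' @param n_components,n_iter,per_class,gray_threshold Classifier
#'   parameters ([balanced_ensemble()]).
#' @param seed Master seed for the whole run.
#' @param out_dir Output directory for stage artifacts and the JSON report.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "spectra_dir",
                                           "binned_csv"),
                            input_path = NULL, cohort_path = NULL,
                            n_patients = 106, prop_deceased = 26 / 106,
                            hazard_ratio = 5.71, baseline_hazard = 0.02,
                            censor_time = 8, dilution_cv = 0.15,
                            noise_sd = 0.002, effect_scale = 1,
                            bin_width = 0.02, bin_range = c(0.2, 10),
                            calibrate = TRUE,
                            n_components = 7, n_iter = 100, per_class = 25,
                            gray_threshold = 0.10, seed = 1L,
                            out_dir = tempfile("nmrisk_run_")) {
  input_mode <- match.arg(input_mode)
  if (input_mode != "synthetic") {
    if (is.null(input_path)) stopf("input_path required for mode '%s'", input_mode)
    if (is.null(cohort_path)) stopf("cohort_path required for mode '%s'", input_mode)
  }
  cfg <- list(input_mode = input_mode, input_path = input_path,
              cohort_path = cohort_path, n_patients = n_patients,
              prop_deceased = prop_deceased, hazard_ratio = hazard_ratio,
              baseline_hazard = baseline_hazard, censor_time = censor_time,
              dilution_cv = dilution_cv, noise_sd = noise_sd,
              effect_scale = effect_scale, bin_width = bin_width,
              bin_range = bin_range, calibrate = calibrate,
              n_components = n_components, n_iter = n_iter,
              per_class = per_class, gray_threshold = gray_threshold,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config A `pipeline_config`.
#' @param overrides Named list of values overriding the file's keys (the
#'   flags-over-config convention).
#' @return A `pipeline_config` (read) or invisibly `path` (write).
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full fingerprinting pipeline
#'
#' Executes generate/load -> calibrate -> bin -> PQN -> balanced PLS-DA
#' ensemble -> majority vote -> risk scores -> Kaplan-Meier/log-rank/Cox ->
#' feature screening, writing each stage's output (CSV/JSON) under
#' `config$out_dir` plus a machine-readable `report.json` with the headline
#' metrics, the seed, and a hash of the configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (config$input_mode == "synthetic") {
    sc <- run_stage("simulate", sim_config(
      n_patients = config$n_patients, prop_deceased = config$prop_deceased,
      hazard_ratio = config$hazard_ratio,
      baseline_hazard = config$baseline_hazard,
      censor_time = config$censor_time, dilution_cv = config$dilution_cv,
      noise_sd = config$noise_sd, seed = config$seed))
    cohort <- run_stage("simulate", generate_cohort(sc))
    peaks <- dcm_peak_library(effect_scale = config$effect_scale)
    spectra <- run_stage("simulate", generate_spectra(cohort, sc, peaks))
    features <- run_stage("simulate", generate_feature_table(
      cohort, seed = config$seed))
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
  } else {
    cohort <- run_stage("load", read_cohort(config$cohort_path))
    features <- NULL
    spectra <- if (config$input_mode == "spectra_dir")
      run_stage("load", read_spectra(config$input_path)) else NULL
  }

  if (config$input_mode == "binned_csv") {
    binned <- run_stage("load", read_binned_matrix(config$input_path))
  } else {
    if (config$calibrate)
      spectra <- run_stage("calibrate", lapply(spectra, calibrate_ppm))
    binned <- run_stage("bin", bin_spectra(spectra,
                                           bin_width = config$bin_width,
                                           range = config$bin_range))
  }
  normalized <- run_stage("normalize", pqn_normalize(binned))
  write_binned_matrix(normalized, file.path(config$out_dir, "binned_pqn.csv"))

  if (!"true_class" %in% names(cohort))
    stopf("pipeline stage 'classify' failed: cohort lacks a class column")
  ord <- match(rownames(normalized$values), cohort$patient_id)
  if (anyNA(ord))
    stopf("pipeline stage 'classify' failed: sample ids do not match cohort patient ids")
  cohort <- cohort[ord, , drop = FALSE]

  ens <- run_stage("classify", balanced_ensemble(
    normalized, cohort$true_class, n_iter = config$n_iter,
    per_class = config$per_class, n_components = config$n_components,
    gray_threshold = config$gray_threshold, seed = config$seed))
  utils::write.csv(ens$votes, file.path(config$out_dir, "votes.csv"),
                   row.names = FALSE)
  full_fit <- run_stage("classify", fit_pls(normalized, cohort$true_class,
                                            n_components = config$n_components))
  vip <- vip_scores(full_fit)
  utils::write.csv(vip, file.path(config$out_dir, "vip.csv"),
                   row.names = FALSE)

  risks <- run_stage("stratify", risk_table(cohort,
                                            ens$votes$predicted_class))
  utils::write.csv(risks, file.path(config$out_dir, "risk_table.csv"),
                   row.names = FALSE)

  surv <- run_stage("survive", {
    met_high <- risks$metabolomics == "high"
    lr_met <- logrank_test(cohort$survival_time, cohort$event, met_high)
    cox_met <- cox_fit(as.numeric(met_high), cohort$survival_time,
                       cohort$event)
    cmb_high <- risks$combined_met_lvef == "high"
    lr_cmb <- logrank_test(cohort$survival_time, cohort$event, cmb_high)
    cox_cmb <- cox_fit(as.numeric(cmb_high), cohort$survival_time,
                       cohort$event)
    km <- list(low = km_estimate(cohort$survival_time[!met_high],
                                 cohort$event[!met_high]),
               high = km_estimate(cohort$survival_time[met_high],
                                  cohort$event[met_high]))
    for (g in names(km))
      utils::write.csv(km[[g]]$table,
                       file.path(config$out_dir,
                                 sprintf("km_metabolomics_%s.csv", g)),
                       row.names = FALSE)
    list(metabolomics = list(hr = unname(cox_met$hr[1]),
                             ci95 = unname(cox_met$ci95[1, ]),
                             logrank_p = lr_met$p_value,
                             lrt_p = cox_met$lrt_p),
         combined_met_lvef = list(hr = unname(cox_cmb$hr[1]),
                                  ci95 = unname(cox_cmb$ci95[1, ]),
                                  logrank_p = lr_cmb$p_value,
                                  lrt_p = cox_cmb$lrt_p))
  })

  screen <- if (!is.null(features)) {
    run_stage("screen", {
      sc_tab <- wilcoxon_screen(features, cohort$true_class)
      utils::write.csv(sc_tab, file.path(config$out_dir, "feature_screen.csv"),
                       row.names = FALSE)
      sc_tab
    })
  } else NULL

  report <- list(
    seed = config$seed,
    config_hash = sum(utf8ToInt(paste(
      vapply(unclass(config)[setdiff(names(config), "out_dir")],
             function(v) paste(format(v), collapse = ","),
             character(1)), collapse = ";"))),
    n_samples = nrow(normalized$values),
    n_bins = ncol(normalized$values),
    ensemble = list(accuracy = ens$metrics$accuracy,
                    sensitivity = ens$metrics$sensitivity,
                    specificity = ens$metrics$specificity,
                    n_gray_zone = sum(ens$votes$gray_zone)),
    n_vip_selected = sum(vip$selected),
    survival = surv,
    n_features_fdr_significant =
      if (!is.null(screen)) sum(screen$p_fdr < 0.05) else NA)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
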