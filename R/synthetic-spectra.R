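#' Peak specification for the synthetic spectrum generator
#'
#' Describes one metabolite's contribution to a 1D 1H spectrum: a multiplet
#' of Lorentzian lines plus a between-class concentration ratio and a
#' between-subject coefficient of variation.
#'
#' @param metabolite_name Label.
#' @param centers Chemical shifts of the multiplet lines (ppm, all within
#'   0.2-10).
#' @param multiplet_intensities Relative line heights (recycled to the length
#'   of `centers`).
#' @param linewidth Full width at half maximum (ppm, > 0).
#' @param class_effect Multiplicative concentration ratio, deceased-class
#'   mean over survivor-class mean (> 0).
#' @param cv Between-subject coefficient of variation (>= 0).
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(metabolite_name, centers, multiplet_intensities = 1,
                      linewidth = 0.004, class_effect = 1, cv = 0.2) {
  if (any(centers < 0.2 | centers > 10))
    stopf("peak '%s': centers must lie within 0.2-10 ppm", metabolite_name)
  if (linewidth <= 0) stopf("peak '%s': linewidth must be > 0", metabolite_name)
  if (class_effect <= 0) stopf("peak '%s': class_effect must be > 0",
                               metabolite_name)
  if (cv < 0) stopf("peak '%s': cv must be >= 0", metabolite_name)
  h <- rep_len(multiplet_intensities, length(centers))
  structure(list(metabolite_name = metabolite_name, centers = centers,
                 multiplet_intensities = h, linewidth = linewidth,
                 class_effect = class_effect, cv = cv),
            class = "peak_spec")
}

#' Default serum peak library
#'
#' Lorentzian line library used by the spectrum generator. The informative
#' metabolites and their directions mirror what the fingerprint classifier is
#' expected to exploit: lower creatine and higher trimethylamine-N-oxide
#' (TMAO), creatinine and lactate in the deceased class, with broad
#' lipoprotein humps at 0.85 and 1.25 ppm (0.05 ppm wide). The anomeric
#' glucose doublet at 5.24 ppm is included as the chemical-shift calibration
#' reference.
#'
#' @param effect_scale Exponent applied to every informative class effect
#'   (`ratio^effect_scale`); 1 gives the default effect sizes, 0 makes the
#'   two classes identical in distribution, values > 1 separate them more.
#' @param cv Between-subject coefficient of variation applied to all peaks.
#' @return List of [peak_spec()] objects.
#' @export
dcm_peak_library <- function(effect_scale = 1, cv = 0.2) {
  e <- function(r) r^effect_scale
  list(
    peak_spec("creatine", c(3.03, 3.93), c(3, 2), class_effect = e(0.70), cv = cv),
    peak_spec("creatinine", c(3.05, 4.06), c(3, 2), class_effect = e(1.40), cv = cv),
    peak_spec("trimethylamine_N_oxide", 3.27, 9, class_effect = e(1.50), cv = cv),
    peak_spec("lactate", c(1.32, 1.34, 4.11, 4.13, 4.15), c(3, 3, 0.5, 1.5, 0.5),
              class_effect = e(1.30), cv = cv),
    # calibration reference: dominant line exactly at 5.24 ppm
    peak_spec("glucose_anomeric", c(5.24, 5.26), c(1.5, 1), cv = cv),
    peak_spec("alanine", c(1.47, 1.49), c(3, 3), cv = cv),
    peak_spec("citrate", c(2.54, 2.66), c(2, 2), cv = cv),
    peak_spec("acetate", 1.92, 3, cv = cv),
    peak_spec("valine", c(0.99, 1.04), c(3, 3), cv = cv),
    peak_spec("glycine", 3.56, 2, cv = cv),
    peak_spec("lipoprotein_CH3", 0.85, 8, linewidth = 0.05,
              class_effect = e(1.20), cv = cv),
    peak_spec("lipoprotein_CH2", 1.25, 12, linewidth = 0.05,
              class_effect = e(1.20), cv = cv),
    # broad macromolecular envelope (protein/lipid background): serum
    # spectra carry signal across the whole range, not just at sharp lines
    peak_spec("macromolecular_background",
              c(0.9, 1.7, 2.5, 3.3, 4.1, 6.0, 7.0, 8.0, 9.0),
              0.06, linewidth = 1.5, class_effect = 1, cv = cv / 4)
  )
}

#' Default ppm grid
#'
#' Ascending grid over 0.2-10 ppm at 1e-3 ppm resolution (9801 points).
#' @return Numeric vector.
#' @export
default_ppm_grid <- function() seq(0.2, 10, by = 0.001)

# Height-normalized Lorentzian lineshape.
lorentzian <- function(x, center, fwhm) {
  g <- fwhm / 2
  g^2 / ((x - center)^2 + g^2)
}

#' Generate one synthetic 1D spectrum
#'
#' Sum of Lorentzian multiplets with per-metabolite lognormal concentration
#' draws (deceased-class means multiplied by each peak's `class_effect`),
#' scaled by an overall dilution factor, plus additive Gaussian noise.
#'
#' @param true_class `"survivor"` or `"deceased"`.
#' @param peaks List of [peak_spec()] objects (non-empty).
#' @param dilution Positive overall scale factor.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param ppm_grid Strictly increasing grid within 0.2-10 ppm.
#' @param seed Integer seed; the concentration draws depend on the seed only,
#'   so two calls differing solely in `dilution` are exactly proportional at
#'   `noise_sd = 0`.
#' @param sample_id Label attached to the spectrum.
#' @return An object of class `spectrum`: list with `ppm`, `intensity`,
#'   `sample_id`.
#' @export
generate_spectrum <- function(true_class, peaks = dcm_peak_library(),
                              dilution = 1, noise_sd = 0,
                              ppm_grid = default_ppm_grid(), seed = 1L,
                              sample_id = "S1") {
  if (length(peaks) == 0) stopf("empty peak library")
  if (is.unsorted(ppm_grid, strictly = TRUE))
    stopf("ppm_grid must be strictly increasing")
  if (dilution <= 0) stopf("dilution must be > 0")
  true_class <- match.arg(true_class, c("survivor", "deceased"))
  intensity <- with_seed(seed, {
    y <- numeric(length(ppm_grid))
    for (pk in peaks) {
      m <- if (true_class == "deceased") pk$class_effect else 1
      conc <- rlnorm_meancv(1, m, pk$cv)
      for (j in seq_along(pk$centers)) {
        y <- y + conc * pk$multiplet_intensities[j] *
          lorentzian(ppm_grid, pk$centers[j], pk$linewidth)
      }
    }
    y <- dilution * y
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    y
  })
  new_spectrum(ppm_grid, intensity, sample_id)
}

#' Generate spectra for a whole cohort
#'
#' One spectrum per cohort row, using each patient's latent `dilution` and a
#' per-patient seed substream.
#'
#' @param cohort Cohort table from [generate_cohort()].
#' @param config The [sim_config()] used to build the cohort (supplies
#'   `noise_sd` and the master seed).
#' @param peaks Peak library.
#' @param ppm_grid ppm axis shared by all spectra.
#' @return Named list of `spectrum` objects (names = patient ids).
#' @export
generate_spectra <- function(cohort, config, peaks = dcm_peak_library(),
                             ppm_grid = default_ppm_grid()) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    generate_spectrum(cohort$true_class[i], peaks,
                      dilution = cohort$dilution[i],
                      noise_sd = config$noise_sd, ppm_grid = ppm_grid,
                      seed = derive_seed(config$seed, 2L, i),
                      sample_id = cohort$patient_id[i])
  })
  names(out) <- cohort$patient_id
  out
}
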