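#' Published baseline counts of the motivating DCM cohort
#'
#' Integer counts from the published baseline-characteristics table of the
#' dilated-cardiomyopathy cohort this package's defaults emulate: 106
#' patients, of whom 80 were alive and 26 dead of heart-failure causes at
#' the end of follow-up, with NYHA class, sex, beta-blocker and diuretic
#' use broken down by vital status. These counts serve as inputs for
#' reproducing the cohort's headline percentages with the summary
#' machinery.
#'
#' @return List with `n`, `alive`, `deceased`, and per-status count vectors
#'   `nyha` (classes I-IV), `male`, `diuretic`, `beta_blocker`.
#' @export
dcm_reference_counts <- function() {
  list(n = 106L, alive = 80L, deceased = 26L,
       nyha = list(alive = c(I = 31L, II = 41L, III = 8L, IV = 0L),
                   deceased = c(I = 7L, II = 12L, III = 5L, IV = 2L)),
       male = c(alive = 55L, deceased = 19L),
       diuretic = c(alive = 51L, deceased = 24L),
       beta_blocker = c(alive = 73L, deceased = 25L))
}

#' Expand the published counts to a patient-level categorical table
#'
#' Builds a patient-level data frame whose categorical columns reproduce
#' [dcm_reference_counts()] exactly (the within-status joint arrangement of
#' unrelated variables is arbitrary; marginal counts per status are exact),
#' suitable for [cohort_summary()]-style tabulations of the published
#' percentages.
#'
#' @return Data frame with `patient_id`, `event` (1 = deceased), `nyha`,
#'   `sex`, `diuretic`, `beta_blocker`.
#' @export
dcm_reference_cohort <- function() {
  rc <- dcm_reference_counts()
  expand_status <- function(status, n_status) {
    nyha <- rep(names(rc$nyha[[status]]), rc$nyha[[status]])
    sex <- rep(c("M", "F"),
               c(rc$male[[status]], n_status - rc$male[[status]]))
    diu <- rep(c("yes", "no"),
               c(rc$diuretic[[status]], n_status - rc$diuretic[[status]]))
    bb <- rep(c("yes", "no"),
              c(rc$beta_blocker[[status]], n_status - rc$beta_blocker[[status]]))
    data.frame(event = as.integer(status == "deceased"), nyha = nyha,
               sex = sex, diuretic = diu, beta_blocker = bb,
               stringsAsFactors = FALSE)
  }
  out <- rbind(expand_status("alive", rc$alive),
               expand_status("deceased", rc$deceased))
  out <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(out))), out)
  out
}
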