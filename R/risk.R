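#' LVEF risk class
#'
#' European-guideline ejection-fraction classes: reduced LVEF (< 40%,
#' high-risk `"HiR"`), mid-range (40-49%, intermediate `"IR"`), preserved
#' (>= 50%, low-risk `"LR"`).
#'
#' @param lvef Left-ventricular ejection fraction, percent, in (0, 100).
#' @return `"HiR"`, `"IR"` or `"LR"` (vectorized).
#' @examples
#' lvef_classify(c(37.5, 46, 50, 40))
#' @export
lvef_classify <- function(lvef) {
  if (any(lvef <= 0 | lvef >= 100)) stopf("lvef must lie in (0, 100)")
  out <- ifelse(lvef < 40, "HiR", ifelse(lvef < 50, "IR", "LR"))
  if (length(out) == 1) out[[1]] else out
}

#' NT-proBNP risk class
#'
#' High risk iff the value strictly exceeds the threshold (default
#' 400 pg/ml).
#'
#' @param value NT-proBNP, pg/ml (>= 0).
#' @param threshold Cutoff (strict `>`).
#' @return `"high"` or `"low"` (vectorized).
#' @export
ntprobnp_classify <- function(value, threshold = 400) {
  if (any(value < 0)) stopf("NT-proBNP must be >= 0")
  ifelse(value > threshold, "high", "low")
}

#' Combined metabolomics x LVEF risk score
#'
#' Metabolomics is the first screen (survivor -> low risk, deceased ->
#' high), then ejection fraction overrides where it is most prognostic:
#' survivor-predicted patients with LVEF < 35% are reclassified high-risk,
#' deceased-predicted patients with LVEF > 50% are reclassified low-risk.
#' For intermediate LVEF the metabolomic class governs. Both boundaries are
#' strict.
#'
#' @param metab_class `"survivor"`/`"deceased"` (vectorized).
#' @param lvef LVEF percent.
#' @return Data frame with `risk_class` (`"low"`/`"high"`) and `provenance`
#'   (which rule fired).
#' @examples
#' combine_met_lvef(c("survivor", "deceased", "deceased"), c(30, 55, 45))
#' @export
combine_met_lvef <- function(metab_class, lvef) {
  if (!all(metab_class %in% c("survivor", "deceased")))
    stopf("metab_class must be 'survivor' or 'deceased'")
  if (any(lvef <= 0 | lvef >= 100)) stopf("lvef must lie in (0, 100)")
  n <- max(length(metab_class), length(lvef))
  metab_class <- rep_len(metab_class, n); lvef <- rep_len(lvef, n)
  risk <- ifelse(metab_class == "deceased", "high", "low")
  prov <- rep("metabolomics", n)
  up <- metab_class == "survivor" & lvef < 35
  dn <- metab_class == "deceased" & lvef > 50
  risk[up] <- "high"; prov[up] <- "LVEF<35 override"
  risk[dn] <- "low"; prov[dn] <- "LVEF>50 override"
  data.frame(risk_class = risk, provenance = prov, stringsAsFactors = FALSE)
}

#' Combined metabolomics x NT-proBNP risk score
#'
#' The combination rule is a named, configurable strategy:
#' `"either_high"` (default) marks a patient high-risk if either source
#' does; `"both_high"` requires both; `"met_only"` and `"ntprobnp_only"`
#' pass one source through.
#'
#' @param metab_class `"survivor"`/`"deceased"`.
#' @param ntprobnp_class `"low"`/`"high"` (from [ntprobnp_classify()]).
#' @param rule Strategy name.
#' @return Character vector `"low"`/`"high"`.
#' @export
combine_met_ntprobnp <- function(metab_class, ntprobnp_class,
                                 rule = c("either_high", "both_high",
                                          "met_only", "ntprobnp_only")) {
  rule <- match.arg(rule)
  if (!all(metab_class %in% c("survivor", "deceased")))
    stopf("metab_class must be 'survivor' or 'deceased'")
  if (!all(ntprobnp_class %in% c("low", "high")))
    stopf("ntprobnp_class must be 'low' or 'high'")
  n <- max(length(metab_class), length(ntprobnp_class))
  m <- rep_len(metab_class, n) == "deceased"
  b <- rep_len(ntprobnp_class, n) == "high"
  hi <- switch(rule,
               either_high = m | b,
               both_high = m & b,
               met_only = m,
               ntprobnp_only = b)
  ifelse(hi, "high", "low")
}

#' Per-patient risk assignments from every source
#'
#' Applies all classifiers to a cohort plus its ensemble metabolomic
#' classes and assembles one risk table (one column per source), the input
#' to the survival comparisons.
#'
#' @param cohort Cohort table.
#' @param metab_class Metabolomic predicted classes
#'   (`"survivor"`/`"deceased"`), aligned with `cohort` rows.
#' @param ntprobnp_threshold Cutoff for [ntprobnp_classify()].
#' @return Data frame: `patient_id`, `metabolomics` (low/high), `lvef`
#'   (LR/IR/HiR), `ntprobnp` (low/high), `combined_met_lvef`,
#'   `combined_met_ntprobnp`, `combined_provenance`.
#' @export
risk_table <- function(cohort, metab_class, ntprobnp_threshold = 400) {
  stopifnot(nrow(cohort) == length(metab_class))
  cmb <- combine_met_lvef(metab_class, cohort$lvef)
  nt <- ntprobnp_classify(cohort$nt_probnp, ntprobnp_threshold)
  data.frame(patient_id = cohort$patient_id,
             metabolomics = ifelse(metab_class == "deceased", "high", "low"),
             lvef = vapply(cohort$lvef, lvef_classify, character(1)),
             ntprobnp = nt,
             combined_met_lvef = cmb$risk_class,
             combined_met_ntprobnp = combine_met_ntprobnp(metab_class, nt),
             combined_provenance = cmb$provenance,
             stringsAsFactors = FALSE)
}
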