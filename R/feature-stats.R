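#' Univariate Wilcoxon screen with Benjamini-Hochberg correction
#'
#' Two-sided Wilcoxon rank-sum test per feature between two groups (exact
#' when both groups have <= 10 observations and no ties, normal
#' approximation with tie/continuity correction otherwise), with BH false
#' discovery rate adjustment across all features jointly. Direction is the
#' sign of (deceased median - survivor median).
#'
#' @param features Data frame or matrix of numeric features (an optional
#'   `patient_id` column is ignored).
#' @param group Two-level labels aligned with rows; the level named by
#'   `positive` is the "deceased" side for the direction sign.
#' @param positive Label treated as the deceased/high-risk group.
#' @return Data frame: `feature`, `p_raw`, `p_fdr`, `direction`,
#'   `median_positive`, `median_negative`.
#' @export
wilcoxon_screen <- function(features, group, positive = "deceased") {
  if (is.data.frame(features) && "patient_id" %in% names(features))
    features <- features[, setdiff(names(features), "patient_id"),
                         drop = FALSE]
  features <- as.data.frame(features)
  group <- as.character(group)
  u <- unique(group)
  if (length(u) != 2) stopf("group must have exactly 2 levels")
  if (!positive %in% u) stopf("positive level '%s' absent", positive)
  ia <- group == positive
  if (sum(ia) < 2 || sum(!ia) < 2) stopf("each group needs >= 2 members")
  res <- lapply(names(features), function(f) {
    xa <- features[[f]][ia]; xb <- features[[f]][!ia]
    if (stats::var(c(xa, xb)) == 0) {
      warnf("feature '%s' is constant; p set to 1", f)
      p <- 1
    } else {
      exact <- length(xa) <= 10 && length(xb) <= 10 &&
        !anyDuplicated(c(xa, xb))
      p <- suppressWarnings(
        stats::wilcox.test(xa, xb, exact = exact, correct = TRUE)$p.value)
    }
    data.frame(feature = f, p_raw = p,
               direction = sign(stats::median(xa) - stats::median(xb)),
               median_positive = stats::median(xa),
               median_negative = stats::median(xb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out[, c("feature", "p_raw", "p_fdr", "direction", "median_positive",
          "median_negative")]
}

#' Tertile assignment
#'
#' Cuts a feature at its empirical 1/3 and 2/3 quantiles (type-7 linear
#' interpolation); ties at a cut go to the lower tertile (intervals closed
#' on the right).
#'
#' @param values Numeric vector.
#' @return Integer vector in 1..3.
#' @export
tertile_cut <- function(values) {
  qs <- stats::quantile(values, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  for (q in qs) {
    if (sum(values == q) > length(values) / 3)
      stopf("tie-degenerate tertiles: cut value %g spans more than a third of samples",
            q)
  }
  tert <- 1L + (values > qs[1]) + (values > qs[2])
  if (any(tabulate(tert, 3) == 0))
    stopf("tie-degenerate tertiles: an empty tertile after tie resolution")
  tert
}

#' Tertile-based Cox association for one feature
#'
#' Indicator covariates for the 2nd and 3rd tertile (reference: 1st) are
#' passed to [cox_fit()]; the adjusted variant appends the clinical
#' covariate specification columns ([clinical_covariates()]).
#'
#' @param values Feature values (non-constant, n >= 9).
#' @param times,events Survival outcome.
#' @param covariates Optional adjustment matrix (e.g.
#'   `clinical_covariates(cohort)`); `NULL` for the univariate model.
#' @param feature Label used in error messages.
#' @param ... Passed to [cox_fit()].
#' @return List with `tertile_hr` (HR for tertiles 2 and 3 vs 1),
#'   `tertile_p` (Wald p-values), `fit` (the `cox_fit`), `tertiles`.
#' @export
tertile_cox <- function(values, times, events, covariates = NULL,
                        feature = "feature", ...) {
  if (length(values) < 9) stopf("tertile Cox needs n >= 9")
  if (stats::var(values) == 0) stopf("feature '%s' is constant", feature)
  tert <- tryCatch(tertile_cut(values), error = function(e)
    stopf("feature '%s': %s", feature, conditionMessage(e)))
  x <- cbind(tertile2 = as.numeric(tert == 2L),
             tertile3 = as.numeric(tert == 3L))
  if (!is.null(covariates)) x <- cbind(x, as.matrix(covariates))
  fit <- cox_fit(x, times, events, ...)
  z <- fit$coefficients[1:2] / fit$se[1:2]
  list(tertile_hr = fit$hr[1:2],
       tertile_p = 2 * stats::pnorm(-abs(z)),
       fit = fit, tertiles = tert)
}

#' Winsorized (robust) correlation
#'
#' Both vectors are winsorized at the `gamma` and `1 - gamma` empirical
#' order statistics (each tail's `floor(gamma * n)` most extreme values
#' replaced by the nearest retained order statistic), then Pearson
#' correlation is taken. The p-value uses the t-type statistic
#' `r * sqrt((h - 2) / (1 - r^2))` on `h - 2` degrees of freedom, where
#' `h = n - 2 * floor(gamma * n)` is the number of untrimmed observations.
#' `gamma = 0` reduces exactly to plain Pearson correlation.
#'
#' @param x,y Numeric vectors, n >= 5, finite.
#' @param gamma Winsorization fraction per tail (default 0.10).
#' @return List with `r`, `p_value`, `df`, `n`.
#' @export
winsorized_correlation <- function(x, y, gamma = 0.10) {
  n <- length(x)
  if (n < 5 || length(y) != n) stopf("need two equal-length vectors, n >= 5")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  g <- floor(gamma * n)
  wins <- function(v) {
    vs <- sort(v)
    pmin(pmax(v, vs[g + 1]), vs[n - g])
  }
  xw <- wins(x); yw <- wins(y)
  if (stats::sd(xw) == 0 || stats::sd(yw) == 0)
    stopf("undefined correlation: zero variance after winsorizing")
  r <- stats::cor(xw, yw)
  h <- n - 2 * g
  df <- h - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p_value = 2 * stats::pt(-abs(tstat), df), df = df, n = n)
}

#' Winsorized correlation matrix with FDR adjustment
#'
#' Pairwise [winsorized_correlation()] between the columns of two tables,
#' with Benjamini-Hochberg adjustment across the whole pair matrix.
#'
#' @param a,b Numeric data frames/matrices with matching rows.
#' @param gamma Winsorization fraction.
#' @return Data frame: `var_a`, `var_b`, `r`, `p_raw`, `p_fdr`.
#' @export
winsorized_correlation_matrix <- function(a, b, gamma = 0.10) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  grid <- expand.grid(var_a = names(a), var_b = names(b),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    w <- winsorized_correlation(a[[grid$var_a[i]]], b[[grid$var_b[i]]], gamma)
    data.frame(var_a = grid$var_a[i], var_b = grid$var_b[i], r = w$r,
               p_raw = w$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

# Scaled median absolute deviation by default (consistency constant
# 1.4826); set scale = 1 for the raw MAD.
mad_stat <- function(x, scale = stats::qnorm(0.75)^-1) {
  stats::median(abs(x - stats::median(x))) * scale
}

#' Baseline-characteristics summary table
#'
#' Median (MAD) for continuous variables and n (%) for categorical ones,
#' reported for the overall cohort and for the alive/deceased groups, with
#' a group-difference p-value per row (Wilcoxon for continuous; chi-square,
#' or Fisher's exact test when any expected cell count is below 5, for
#' categorical) and Benjamini-Hochberg adjustment across rows. Percentages
#' are reported to one decimal.
#'
#' @param cohort Cohort table; group membership comes from the `event`
#'   column (1 = deceased).
#' @param continuous,categorical Column names to summarize.
#' @param scaled_mad Use the 1.4826-scaled MAD (default) or the raw median
#'   absolute deviation.
#' @return Data frame of class `cohort_summary`: one row per variable (or
#'   per categorical level) with formatted `overall`/`alive`/`deceased`
#'   cells, numeric `pct_overall`/`pct_alive`/`pct_deceased` for
#'   categorical rows, and `p`/`p_fdr`.
#' @export
cohort_summary <- function(cohort,
                           continuous = c("age_at_diagnosis",
                                          "time_from_diagnosis", "sbp",
                                          "eddi", "lavi", "lvef",
                                          "nt_probnp"),
                           categorical = c("sex", "nyha"),
                           scaled_mad = TRUE) {
  if (!"event" %in% names(cohort)) stopf("cohort must carry an 'event' column")
  alive <- cohort$event == 0
  if (!any(alive) || all(alive)) stopf("both alive and deceased groups required")
  scl <- if (scaled_mad) stats::qnorm(0.75)^-1 else 1
  continuous <- intersect(continuous, names(cohort))
  categorical <- intersect(categorical, names(cohort))
  rows <- list()
  fmt_med <- function(x) sprintf("%.1f (%.1f)", stats::median(x),
                                 mad_stat(x, scl))
  for (v in continuous) {
    x <- cohort[[v]]
    p <- suppressWarnings(stats::wilcox.test(x[alive], x[!alive])$p.value)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "", type = "continuous",
      overall = fmt_med(x), alive = fmt_med(x[alive]),
      deceased = fmt_med(x[!alive]),
      pct_overall = NA_real_, pct_alive = NA_real_, pct_deceased = NA_real_,
      p = p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- as.factor(cohort[[v]])
    tab <- table(x, factor(ifelse(alive, "alive", "deceased"),
                           levels = c("alive", "deceased")))
    p <- if (nlevels(x) < 2) NA_real_ else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5))
        stats::fisher.test(tab)$p.value
      else suppressWarnings(stats::chisq.test(tab)$p.value)
    }
    for (lv in levels(x)) {
      pct <- function(sel) {
        k <- sum(x[sel] == lv); n <- sum(sel)
        list(str = sprintf("%d (%.1f)", k, round(100 * k / n, 1)),
             num = round(100 * k / n, 1))
      }
      all_ <- pct(rep(TRUE, length(x))); al <- pct(alive); de <- pct(!alive)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lv, type = "categorical",
        overall = all_$str, alive = al$str, deceased = de$str,
        pct_overall = all_$num, pct_alive = al$num, pct_deceased = de$num,
        p = if (lv == levels(x)[1]) p else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  has_p <- !is.na(out$p)
  out$p_fdr <- NA_real_
  out$p_fdr[has_p] <- stats::p.adjust(out$p[has_p], method = "BH")
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Group share of a cohort, percent to one decimal
#'
#' Convenience for headline proportions (e.g. survivor and deceased
#' percentages, NYHA I-II share).
#'
#' @param k Count in the subgroup.
#' @param n Total count.
#' @return Percentage rounded to one decimal.
#' @export
cohort_percent <- function(k, n) round(100 * k / n, 1)
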