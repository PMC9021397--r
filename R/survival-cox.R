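# Breslow/Efron partial log-likelihood, score vector and observed
# information for right-censored data. `x` is n x p, already sorted jobs are
# handled internally. Returns list(loglik, U, I).
cox_loglik <- function(beta, x, times, events, tie_method = "breslow") {
  n <- nrow(x); p <- ncol(x)
  o <- order(times)
  x <- x[o, , drop = FALSE]; times <- times[o]; events <- events[o]
  eta <- as.numeric(x %*% beta)
  r <- exp(eta)
  # suffix sums over the risk set {j : t_j >= t_i}
  revcum <- function(v) rev(cumsum(rev(v)))
  S0 <- revcum(r)
  S1 <- apply(x * r, 2, revcum)
  S1 <- matrix(S1, nrow = n)
  # S2 upper-triangular pairs
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  S2flat <- vapply(seq_len(nrow(pairs)), function(k)
    revcum(r * x[, pairs[k, 1]] * x[, pairs[k, 2]]), numeric(n))
  S2flat <- matrix(S2flat, nrow = n)
  get_S2 <- function(i) {
    m <- matrix(0, p, p)
    m[cbind(pairs[, 1], pairs[, 2])] <- S2flat[i, ]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  ll <- 0; U <- numeric(p); Imat <- matrix(0, p, p)
  dt <- unique(times[events == 1])
  for (t in dt) {
    idx <- which(times == t & events == 1)
    i0 <- which(times >= t)[1]   # first index of the risk set
    d <- length(idx)
    xsum <- colSums(x[idx, , drop = FALSE])
    s0 <- S0[i0]; s1 <- S1[i0, ]; s2 <- get_S2(i0)
    if (tie_method == "breslow" || d == 1) {
      ll <- ll + sum(eta[idx]) - d * log(s0)
      U <- U + xsum - d * s1 / s0
      Imat <- Imat + d * (s2 / s0 - tcrossprod(s1 / s0))
    } else {
      # Efron: deflate the tied deaths' own contribution progressively
      rd <- sum(r[idx])
      s1d <- colSums(x[idx, , drop = FALSE] * r[idx])
      s2d <- crossprod(x[idx, , drop = FALSE] * r[idx],
                       x[idx, , drop = FALSE])
      ll <- ll + sum(eta[idx])
      for (j in seq_len(d) - 1) {
        f <- j / d
        s0j <- s0 - f * rd
        s1j <- s1 - f * s1d
        s2j <- s2 - f * s2d
        ll <- ll - log(s0j)
        U <- U + xsum / d - s1j / s0j
        Imat <- Imat + s2j / s0j - tcrossprod(s1j / s0j)
      }
    }
  }
  list(loglik = ll, U = U, I = Imat)
}

#' Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood, with Breslow
#' (default) or Efron handling of tied death times. Wald 95% confidence
#' intervals come from the inverse observed information on the log-hazard
#' scale, and overall significance from the likelihood-ratio test against
#' the null model (chi-square, df = number of coefficients).
#'
#' @param x Covariate matrix (numeric, n x p), data frame, or numeric
#'   vector; data-frame factor columns are expanded to treatment-contrast
#'   indicators.
#' @param times Follow-up times.
#' @param events Event indicator (1 = death, 0 = censored).
#' @param tie_method `"breslow"` or `"efron"`.
#' @param max_iter,tol Newton-Raphson iteration cap and relative
#'   log-likelihood convergence tolerance.
#' @return Object of class `cox_fit`: `coefficients`, `hr` (`exp(coef)`),
#'   `se`, `ci95` (matrix, log-hazard-scale Wald exponentiated),
#'   `loglik`, `loglik_null`, `lrt_stat`, `lrt_p`, `tie_method`,
#'   `n`, `n_events`, `iterations`, `monotone` (perfect-separation flag).
#' @examples
#' set.seed(1)
#' g <- rep(0:1, each = 50)
#' t <- rexp(100, 0.1 * exp(log(3) * g))
#' fit <- cox_fit(g, pmin(t, 10), as.integer(t <= 10))
#' fit$hr
#' @export
cox_fit <- function(x, times, events, tie_method = c("breslow", "efron"),
                    max_iter = 50, tol = 1e-9) {
  tie_method <- match.arg(tie_method)
  if (is.data.frame(x)) {
    mm <- stats::model.matrix(~ ., data = x)
    x <- mm[, -1, drop = FALSE]
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(times) || length(times) != length(events))
    stopf("x, times and events must have matching lengths")
  if (sum(events) < 1) stopf("Cox fit needs at least one event")
  const <- apply(x, 2, function(col) stats::var(col) == 0)
  if (any(const))
    stopf("covariate(s) constant across all samples: %s",
          paste(colnames(x)[const], collapse = ", "))
  p <- ncol(x)
  beta <- numeric(p)
  fit0 <- cox_loglik(beta, x, times, events, tie_method)
  ll_null <- fit0$loglik
  ll_old <- ll_null
  cur <- fit0
  iter <- 0
  repeat {
    iter <- iter + 1
    step <- tryCatch(solve(cur$I, cur$U), error = function(e)
      qr.solve(cur$I, cur$U, tol = 1e-14))
    beta_new <- beta + step
    fit_new <- cox_loglik(beta_new, x, times, events, tie_method)
    halvings <- 0
    while (!is.finite(fit_new$loglik) || fit_new$loglik < ll_old - 1e-12) {
      halvings <- halvings + 1
      if (halvings > 30) break
      beta_new <- (beta + beta_new) / 2
      fit_new <- cox_loglik(beta_new, x, times, events, tie_method)
    }
    beta <- beta_new; cur <- fit_new
    if (abs(cur$loglik - ll_old) <
        tol * (abs(ll_old) + tol) || iter >= max_iter) break
    ll_old <- cur$loglik
  }
  if (iter >= max_iter &&
      sqrt(sum(cur$U^2)) > 1e-3)
    stopf("Cox fit did not converge in %d iterations (gradient norm %.3g)",
          max_iter, sqrt(sum(cur$U^2)))
  monotone <- any(abs(beta) > 15)
  if (monotone)
    warnf("monotone partial likelihood suspected (|coef| > 15): possible perfect separation")
  vcov <- tryCatch(solve(cur$I), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(0.975)
  ci <- cbind(lower = exp(beta - z * se), upper = exp(beta + z * se))
  rownames(ci) <- colnames(x)
  lrt <- 2 * (cur$loglik - ll_null)
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 hr = stats::setNames(exp(beta), colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 ci95 = ci, vcov = vcov,
                 loglik = cur$loglik, loglik_null = ll_null,
                 lrt_stat = lrt,
                 lrt_p = stats::pchisq(lrt, p, lower.tail = FALSE),
                 tie_method = tie_method, n = nrow(x),
                 n_events = sum(events), iterations = iter,
                 monotone = monotone),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s\n", x$n, x$n_events,
              x$tie_method))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    `CI95 lower` = x$ci95[, 1], `CI95 upper` = x$ci95[, 2],
                    check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("LRT: chi-square %.4g on %d df, p = %.3g\n", x$lrt_stat,
              length(x$coefficients), x$lrt_p))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.cox_fit <- function(object, ...) {
  print(object)
  wald_z <- object$coefficients / object$se
  tab <- data.frame(z = wald_z,
                    p = 2 * stats::pnorm(-abs(wald_z)))
  cat("Wald tests:\n"); print(round(tab, 4))
  invisible(object)
}

#' Likelihood-ratio test for nested Cox models
#'
#' `2 * (loglik_full - loglik_null)` referred to a chi-square distribution
#' with df equal to the number of extra coefficients.
#'
#' @param full A `cox_fit`.
#' @param null_loglik Log partial likelihood of the nested null model
#'   (default: the fit's own null log-likelihood, i.e. all coefficients 0).
#' @param df Degrees of freedom (default: number of coefficients in `full`).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, null_loglik = full$loglik_null,
                                  df = length(full$coefficients)) {
  stopifnot(inherits(full, "cox_fit"))
  stat <- 2 * (full$loglik - null_loglik)
  if (stat < -1e-8)
    stopf("negative likelihood-ratio statistic (%.3g): models are not nested or fit failed",
          stat)
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Score test of H0: beta = 0 (used to cross-check the log-rank statistic).
cox_score_test <- function(x, times, events, tie_method = "breslow") {
  x <- as.matrix(x)
  f <- cox_loglik(numeric(ncol(x)), x, times, events, tie_method)
  stat <- as.numeric(crossprod(f$U, solve(f$I, f$U)))
  list(statistic = stat, df = ncol(x),
       p_value = stats::pchisq(stat, ncol(x), lower.tail = FALSE))
}

#' Clinical covariate specification (dichotomized model matrix)
#'
#' Expands a cohort table into the dichotomized adjustment covariates used
#' in the multivariate survival models: male sex, age at diagnosis > 60
#' years, time from diagnosis > 15 years, NT-proBNP > 400 pg/ml, LVEF class
#' indicators (mid-range 40-49 and reduced < 40, reference preserved >= 50),
#' NYHA II and NYHA III-IV (reference I), SBP > 130 mmHg, EDDi > 30 mm/m^2,
#' LAVi > 40 ml/m^2. All cuts are strict `>` at the boundary.
#'
#' @param cohort Cohort table with the standard columns.
#' @return Numeric 0/1 matrix, one row per patient.
#' @export
clinical_covariates <- function(cohort) {
  lv <- vapply(cohort$lvef, lvef_classify, character(1))
  m <- cbind(
    sex_male = as.numeric(cohort$sex == "M"),
    age_gt60 = as.numeric(cohort$age_at_diagnosis > 60),
    time_gt15 = as.numeric(cohort$time_from_diagnosis > 15),
    ntprobnp_gt400 = as.numeric(cohort$nt_probnp > 400),
    lvef_ir = as.numeric(lv == "IR"),
    lvef_hir = as.numeric(lv == "HiR"),
    nyha_ii = as.numeric(cohort$nyha == "II"),
    nyha_iii_iv = as.numeric(cohort$nyha %in% c("III", "IV")),
    sbp_gt130 = as.numeric(cohort$sbp > 130),
    eddi_gt30 = as.numeric(cohort$eddi > 30),
    lavi_gt40 = as.numeric(cohort$lavi > 40))
  rownames(m) <- cohort$patient_id
  m
}
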