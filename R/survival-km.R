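#' Kaplan-Meier product-limit estimator
#'
#' Step-function survival estimate with the at-risk and cumulative-event
#' counts needed for "number at risk" / "cumulative events" strips under a
#' survival plot. Censorings tied with deaths are, as is conventional,
#' treated as occurring just after them (the censored subject is still in
#' the risk set at that time).
#'
#' @param times Follow-up times (>= 0, years).
#' @param events Event indicator (1 = death, 0 = censored).
#' @return Object of class `km_curve`: data frame `table` with one row per
#'   distinct observed time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, `cum_events`), plus `event_times`, `censor_marks`, `n`.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
#' km$table
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stopf("empty input")
  if (any(times < 0)) stopf("times must be >= 0")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  tab <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv,
                    cum_events = cumsum(n_event))
  structure(list(table = tab,
                 event_times = ut[n_event > 0],
                 censor_marks = ut[n_censor > 0],
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d deaths at %d distinct times\n", x$n,
              sum(x$table$n_event), length(x$event_times)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km A `km_curve`.
#' @param at Times at which to read the step function.
#' @return Survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(km, at) {
  idx <- findInterval(at, km$table$time)
  ifelse(idx == 0, 1, km$table$survival[pmax(idx, 1)])
}

#' At-risk counts at arbitrary times
#'
#' Mirrors the "Number at risk" strip under published survival curves.
#' @param km A `km_curve`.
#' @param at Times.
#' @return Integer counts.
#' @export
km_at_risk_at <- function(km, at) {
  full <- km$table
  vapply(at, function(t) {
    i <- which(full$time >= t)
    if (length(i)) full$n_risk[i[1]] else 0
  }, numeric(1))
}

#' @export
plot.km_curve <- function(x, ..., xlab = "Time (years)",
                          ylab = "Survival probability", col = 1) {
  tb <- x$table
  graphics::plot(c(0, tb$time), c(1, tb$survival), type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, col = col, ...)
  cm <- x$censor_marks
  if (length(cm))
    graphics::points(cm, km_survival_at(x, cm), pch = 3, col = col)
  invisible(x)
}

#' Log-rank test
#'
#' Observed-minus-expected test across k groups with hypergeometric
#' variance, df = k - 1.
#'
#' @param times Follow-up times.
#' @param events Event indicator (1 = death).
#' @param group Group labels (2 or more non-empty groups).
#' @return Object of class `logrank_test`: `statistic` (chi-square), `df`,
#'   `p_value`, `observed`, `expected` per group.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stopf("log-rank needs >= 2 non-empty groups")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  k <- nlevels(group)
  death_times <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k)
  for (t in death_times) {
    at <- times >= t
    n <- sum(at)
    d <- sum(times == t & events == 1)
    if (n <= 1 && d >= n) {
      # last subject(s): no variance contribution
      ng <- vapply(levels(group), function(g) sum(at & group == g), numeric(1))
      dg <- vapply(levels(group), function(g)
        sum(times == t & events == 1 & group == g), numeric(1))
      O <- O + dg; E <- E + d * ng / n
      next
    }
    ng <- vapply(levels(group), function(g) sum(at & group == g), numeric(1))
    dg <- vapply(levels(group), function(g)
      sum(times == t & events == 1 & group == g), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    c_t <- d * (n - d) / (n - 1)
    V <- V + c_t * (diag(ng / n, k) - tcrossprod(ng / n))
  }
  dvec <- (O - E)[-1]
  Vsub <- V[-1, -1, drop = FALSE]
  stat <- tryCatch(as.numeric(crossprod(dvec, solve(Vsub, dvec))),
                   error = function(e)
                     as.numeric(crossprod(dvec,
                                          qr.solve(Vsub, dvec, tol = 1e-12))))
  df <- k - 1
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = O, expected = E, variance = V),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
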