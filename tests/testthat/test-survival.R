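test_that("Kaplan-Meier product-limit matches hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  # S = 2/3 on [1, 3), 0 at 3: (1 - 1/3) then (1 - 1/1)
  expect_equal(km$table$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(km$table$n_risk, c(3, 2, 1))
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$censor_marks, 2)
  expect_equal(km_survival_at(km, c(0.5, 1.5, 10)), c(1, 2 / 3, 0))
  expect_equal(km_at_risk_at(km, c(0, 2.5)), c(3, 1))

  allc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(allc$table$survival == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "times")
})

test_that("Kaplan-Meier equals 1 - ECDF without censoring and matches the survival oracle", {
  set.seed(12)
  t_all <- rexp(80, 0.3)
  km <- km_estimate(t_all, rep(1, 80))
  expect_equal(km$table$survival,
               1 - ecdf(t_all)(km$table$time), tolerance = 1e-12)

  sd <- make_survival_data(n = 200, seed = 12)
  km2 <- km_estimate(sd$time, sd$event)
  sf <- survival::survfit(survival::Surv(sd$time, sd$event) ~ 1)
  expect_lt(max(abs(km_survival_at(km2, sf$time) - sf$surv)), 1e-10)
})

test_that("log-rank test matches hand computation and the survival oracle", {
  # two identical copies of the same group: perfect symmetry
  tm <- c(1, 2, 3, 1, 2, 3); ev <- c(1, 0, 1, 1, 0, 1)
  sym <- logrank_test(tm, ev, rep(c("a", "b"), each = 3))
  expect_equal(sym$statistic, 0, tolerance = 1e-12)
  expect_equal(sym$p_value, 1)

  # single death time, at-risk (2, 2), death in group A only:
  # O - E = 0.5, hypergeometric variance 0.25, chi-square 1
  h <- logrank_test(c(1, 5, 5, 5), c(1, 0, 0, 0), c("A", "A", "B", "B"))
  expect_equal(unname(h$observed - h$expected), c(0.5, -0.5))
  expect_equal(h$statistic, 1, tolerance = 1e-12)

  sd <- make_survival_data(n = 300, seed = 3)
  mine <- logrank_test(sd$time, sd$event, sd$group)
  orc <- survival::survdiff(survival::Surv(sd$time, sd$event) ~ sd$group)
  expect_lt(abs(mine$statistic - orc$chisq), 1e-8)

  # three groups against the oracle
  g3 <- rep(1:3, each = 100)
  mine3 <- logrank_test(sd$time, sd$event, g3)
  orc3 <- survival::survdiff(survival::Surv(sd$time, sd$event) ~ g3)
  expect_lt(abs(mine3$statistic - orc3$chisq), 1e-8)
  expect_equal(mine3$df, 2)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2 non-empty")
})

test_that("log-rank equals the Cox score test at beta = 0 on tie-free data", {
  set.seed(7)
  n <- 150
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.7 * g))
  cens <- runif(n, 1, 12)
  time <- pmin(t, cens); ev <- as.integer(t <= cens)
  lr <- logrank_test(time, ev, g)
  st <- nmrisk:::cox_score_test(matrix(as.numeric(g)), time, ev)
  expect_lt(abs(lr$statistic - st$statistic), 1e-8)
})

test_that("Cox regression matches the survival oracle for both tie methods", {
  set.seed(42)
  n <- 300
  g <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
  t <- rexp(n, 0.08 * exp(0.9 * g - 0.4 * x2))
  cens <- runif(n, 2, 15)
  time <- round(pmin(t, cens), 1)  # induce ties
  ev <- as.integer(t <= cens)
  X <- cbind(g = g, x2 = x2)

  for (ties in c("breslow", "efron")) {
    mine <- cox_fit(X, time, ev, tie_method = ties)
    orc <- survival::coxph(survival::Surv(time, ev) ~ g + x2, ties = ties)
    expect_lt(max(abs(mine$coefficients - coef(orc))), 1e-6)
    expect_lt(abs(mine$loglik - orc$loglik[2]), 1e-6)
    expect_lt(abs(mine$loglik_null - orc$loglik[1]), 1e-8)
    expect_lt(max(abs(mine$se - sqrt(diag(vcov(orc))))), 1e-6)
  }
  mine <- cox_fit(X, time, ev)
  expect_equal(unname(mine$hr), unname(exp(mine$coefficients)))
  expect_gte(mine$loglik, mine$loglik_null)
})

test_that("Cox coefficient agrees with brute-force partial-likelihood maximization", {
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1, 1, 0, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 1)
  # written-out Breslow partial log-likelihood, maximized by golden section
  pl <- function(b) {
    sum(vapply(which(ev == 1), function(i) {
      b * x[i] - log(sum(exp(b * x[tm >= tm[i]])))
    }, numeric(1)))
  }
  bf <- optimize(pl, c(-10, 10), maximum = TRUE)$maximum
  mine <- cox_fit(x, tm, ev)
  expect_lt(abs(unname(mine$coefficients) - bf), 1e-4)
})

test_that("null covariates give small coefficients and honest uncertainty", {
  set.seed(10)
  n <- 1000
  t <- rexp(n, 0.1); cens <- runif(n, 0, 20)
  x <- rnorm(n)
  fit <- cox_fit(x, pmin(t, cens), as.integer(t <= cens))
  expect_lt(abs(unname(fit$coefficients)), 0.1)
  expect_gt(fit$lrt_p, 0.001)
  expect_error(cox_fit(rep(1, n), pmin(t, cens), as.integer(t <= cens)),
               "constant")
  expect_error(cox_fit(x, pmin(t, cens), rep(0, n)), "at least one event")
})

test_that("Cox estimate converges to the true rate ratio at large n", {
  set.seed(20)
  n <- 5000
  g <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.05 * exp(log(4) * g))
  fit <- cox_fit(g, t, rep(1, n))
  expect_lt(abs(unname(fit$hr) - 4) / 4, 0.05)
})

test_that("likelihood-ratio test reduces to its defining identity", {
  sd <- make_survival_data(n = 120, seed = 30)
  fit <- cox_fit(sd$group, sd$time, sd$event)
  lrt <- likelihood_ratio_test(fit)
  expect_equal(lrt$statistic, 2 * (fit$loglik - fit$loglik_null),
               tolerance = 1e-12)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # null model against itself: statistic 0, p = 1
  null_lrt <- likelihood_ratio_test(fit, null_loglik = fit$loglik)
  expect_equal(null_lrt$statistic, 0)
  expect_equal(null_lrt$p_value, 1)
  expect_error(likelihood_ratio_test(fit, null_loglik = fit$loglik + 1),
               "negative")
})

test_that("clinical covariate dichotomization uses strict boundaries", {
  cohort <- data.frame(
    patient_id = c("a", "b"),
    sex = c("M", "F"),
    age_at_diagnosis = c(60, 61),
    time_from_diagnosis = c(15, 16),
    nt_probnp = c(400, 401),
    lvef = c(40, 50),
    nyha = c("II", "IV"),
    sbp = c(130, 131),
    eddi = c(30, 31),
    lavi = c(40, 41), stringsAsFactors = FALSE)
  m <- clinical_covariates(cohort)
  expect_equal(unname(m["a", ]), c(1, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0))
  expect_equal(unname(m["b", ]), c(0, 1, 1, 1, 0, 0, 0, 1, 1, 1, 1))
})
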