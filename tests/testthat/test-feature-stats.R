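test_that("Wilcoxon screen reproduces exact small-sample p-values and BH adjustment", {
  feats <- data.frame(f1 = c(1, 2, 3, 4, 5, 6))
  grp <- c("deceased", "deceased", "deceased",
           "survivor", "survivor", "survivor")
  scr <- wilcoxon_screen(feats, grp)
  # complete separation of ranks: exact two-sided p = 2/choose(6,3) = 0.1
  expect_equal(scr$p_raw, 0.1, tolerance = 1e-12)
  expect_equal(scr$direction, -1)

  # BH step-up on (0.01, 0.02, 0.03, 0.04) adjusts all to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))

  const <- data.frame(flat = rep(1, 6), f1 = c(1, 2, 3, 4, 5, 6))
  expect_warning(scr2 <- wilcoxon_screen(const, grp), "constant")
  expect_equal(scr2$p_raw[scr2$feature == "flat"], 1)
  expect_true(all(scr2$p_fdr >= scr2$p_raw))
})

test_that("BH adjustment is permutation-equivariant", {
  set.seed(3)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(p.adjust(p, "BH")[perm], p.adjust(p[perm], "BH"))
})

test_that("tertile cuts partition values with ties going down", {
  expect_equal(tertile_cut(1:9), rep(1:3, each = 3))
  expect_equal(tertile_cut(c(9:1)), rep(3:1, each = 3))
  # rank replacement leaves assignments unchanged
  set.seed(4)
  v <- rnorm(30)
  expect_equal(tertile_cut(v), tertile_cut(rank(v)))
  expect_error(tertile_cut(c(rep(5, 7), 8:10)), "tie-degenerate")
})

test_that("tertile Cox recovers a hazard that doubles per tertile", {
  # geometric-mean estimate over replicates (a single draw of this size has
  # a log-HR standard error of ~0.13)
  log_hr3 <- vapply(1:5, function(rep) {
    set.seed(14 + rep)
    n <- 600
    v <- runif(n)
    tert <- tertile_cut(v)
    t <- rexp(n, 0.05 * 2^(tert - 1))
    cens <- runif(n, 5, 30)
    res <- tertile_cox(v, pmin(t, cens), as.integer(t <= cens))
    expect_lt(res$tertile_p[["tertile3"]], 0.01)
    log(unname(res$tertile_hr["tertile3"]))
  }, numeric(1))
  est <- exp(mean(log_hr3))
  expect_gt(est, 3.2)
  expect_lt(est, 5.0)

  expect_error(tertile_cox(rep(1, 20), rexp(20), rep(1, 20)), "constant")
  expect_error(tertile_cox(1:5, rexp(5), rep(1, 5)), "n >= 9")
})

test_that("tertile Cox is calibrated under the null", {
  hits <- 0
  for (s in 1:60) {
    set.seed(400 + s)
    n <- 120
    v <- rnorm(n)
    t <- rexp(n, 0.1)
    cens <- runif(n, 2, 20)
    res <- tertile_cox(v, pmin(t, cens), as.integer(t <= cens))
    hits <- hits + all(res$tertile_p > 0.05)
  }
  expect_gte(hits, 0.9 * 60 - 6)  # >= 90% minus binomial slack
})

test_that("adjusted tertile Cox accepts the clinical covariate spec", {
  co <- generate_cohort(sim_config(n_patients = 90, seed = 31,
                                   baseline_hazard = 0.08))
  v <- rnorm(90)
  res <- tertile_cox(v, co$survival_time, co$event,
                     covariates = clinical_covariates(co))
  expect_length(res$fit$coefficients, 2 + 11)
  expect_named(res$tertile_hr, c("tertile2", "tertile3"))
})

test_that("winsorized correlation preserves linearity and reduces to Pearson at gamma 0", {
  set.seed(5)
  x <- rnorm(20)
  wc <- winsorized_correlation(x, 2 * x + 3)
  expect_equal(wc$r, 1, tolerance = 1e-12)

  y <- rnorm(20)
  expect_equal(winsorized_correlation(x, y, gamma = 0)$r, cor(x, y),
               tolerance = 1e-12)

  # affine invariance (positive slope)
  w1 <- winsorized_correlation(x, y)
  w2 <- winsorized_correlation(5 * x - 2, 0.3 * y + 7)
  expect_equal(w1$r, w2$r, tolerance = 1e-12)
  expect_equal(w1$p_value, w2$p_value, tolerance = 1e-12)

  expect_error(winsorized_correlation(1:4, 1:4), "n >= 5")
  expect_error(winsorized_correlation(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 9),
                                      rnorm(10)), "zero variance")
})

test_that("winsorized correlation matches a spreadsheet-style hand computation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, -50)
  g <- floor(0.1 * 10)
  xs <- sort(x); ys <- sort(y)
  xw <- pmin(pmax(x, xs[g + 1]), xs[10 - g])
  yw <- pmin(pmax(y, ys[g + 1]), ys[10 - g])
  r_hand <- (mean(xw * yw) - mean(xw) * mean(yw)) /
    (sqrt(mean(xw^2) - mean(xw)^2) * sqrt(mean(yw^2) - mean(yw)^2))
  wc <- winsorized_correlation(x, y, gamma = 0.1)
  expect_equal(wc$r, r_hand, tolerance = 1e-10)
  expect_equal(wc$df, 10 - 2 * g - 2)
})

test_that("winsorized correlation matrix applies FDR across all pairs", {
  set.seed(6)
  a <- as.data.frame(matrix(rnorm(100), 20, 5))
  b <- as.data.frame(matrix(rnorm(40), 20, 2))
  m <- winsorized_correlation_matrix(a, b)
  expect_equal(nrow(m), 10)
  expect_true(all(m$p_fdr >= m$p_raw))
})

test_that("cohort summary reproduces the published percentages from printed counts", {
  ref <- dcm_reference_cohort()
  expect_equal(nrow(ref), 106)
  expect_equal(cohort_percent(sum(ref$event == 0), nrow(ref)), 75.5)
  expect_equal(cohort_percent(sum(ref$event == 1), nrow(ref)), 24.5)
  expect_equal(cohort_percent(sum(ref$nyha %in% c("I", "II")), nrow(ref)),
               85.8)
  cs <- cohort_summary(ref, continuous = character(0),
                       categorical = c("nyha", "sex", "diuretic"))
  diu <- cs[cs$variable == "diuretic" & cs$level == "yes", ]
  expect_equal(diu$pct_deceased, 92.3)
  nyha12 <- cs[cs$variable == "nyha" & cs$level %in% c("I", "II"), ]
  expect_equal(sum(nyha12$pct_overall), 85.8)
})

test_that("cohort summary formats continuous rows and tests group differences", {
  co <- generate_cohort(sim_config(n_patients = 80, seed = 17,
                                   baseline_hazard = 0.08))
  cs <- cohort_summary(co)
  expect_s3_class(cs, "cohort_summary")
  expect_true(all(c("overall", "alive", "deceased", "p", "p_fdr") %in%
                    names(cs)))
  cont <- cs[cs$type == "continuous", ]
  expect_true(all(grepl("^[0-9.]+ \\([0-9.]+\\)$", cont$overall)))
  expect_true(all(cs$p_fdr >= cs$p, na.rm = TRUE))
  expect_error(cohort_summary(transform(co, event = 0)), "both alive")
})
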