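test_that("PLS separates a column that encodes the class", {
  set.seed(2)
  X <- matrix(rnorm(60), 10, 6)
  y <- rep(c(1, -1), 5)
  X[, 3] <- y
  fit <- fit_pls(X, y, n_components = 1)
  w <- abs(fit$x_weights[, 1])
  expect_equal(which.max(w), 3L)
  expect_equal(sign(predict(fit, X)), y)
})

test_that("NIPALS scores and weights match an established PLS oracle", {
  set.seed(1)
  X <- matrix(rnorm(60), 10, 6)
  y <- rep(c(-1, 1), 5)
  fit <- fit_pls(X, y, n_components = 3)
  orc <- mixOmics::pls(X, matrix(y), ncomp = 3, scale = FALSE,
                       mode = "regression")
  for (a in 1:3) {
    expect_lt(min(max(abs(fit$x_weights[, a] - orc$loadings$X[, a])),
                  max(abs(fit$x_weights[, a] + orc$loadings$X[, a]))), 1e-6)
    expect_lt(min(max(abs(fit$scores[, a] - orc$variates$X[, a])),
                  max(abs(fit$scores[, a] + orc$variates$X[, a]))), 1e-6)
  }
  # successive score vectors mutually orthogonal
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)

  expect_error(fit_pls(X, y, n_components = 0), "n_components")
  expect_error(fit_pls(X, rep(1, 10), 2), "both -1 and \\+1|2 classes")
  expect_error(fit_pls(X, y, n_components = 10), "rank bound")
})

test_that("prediction equals the explicit centered linear form", {
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4)
  y <- c(1, 1, 1, -1, -1, -1)
  fit <- fit_pls(X, y, n_components = 2)

  # brute-force recomputation from stored weights/loadings via deflation
  Xc <- sweep(X, 2, fit$x_mean)
  W <- fit$x_weights; P <- fit$x_loadings; q <- fit$y_loadings
  pred <- rep(fit$y_mean, 6)
  E <- Xc
  for (a in 1:2) {
    t_a <- E %*% W[, a]
    pred <- pred + q[a] * t_a
    E <- E - tcrossprod(t_a, P[, a])
  }
  expect_equal(predict(fit, X), as.numeric(pred), tolerance = 1e-10)
  expect_equal(ifelse(predict(fit, X) > 0, "deceased", "survivor"),
               predict(fit, X, type = "class"))

  # the training-set mean row scores exactly at y_mean
  expect_equal(predict(fit, matrix(colMeans(X), 1)), fit$y_mean,
               tolerance = 1e-12)
  expect_error(predict(fit, matrix(0, 2, 3)), "columns")
})

test_that("first PLS direction is invariant to adding a constant to X", {
  set.seed(4)
  X <- matrix(rnorm(80), 16, 5)
  y <- rep(c(-1, 1), 8)
  f1 <- fit_pls(X, y, 3)
  f2 <- fit_pls(X + 100, y, 3)
  expect_equal(f1$x_weights, f2$x_weights, tolerance = 1e-8)
  expect_equal(f1$coefficient_vector, f2$coefficient_vector, tolerance = 1e-8)
})

test_that("VIP satisfies its algebraic identity and matches brute force", {
  set.seed(5)
  X <- matrix(rnorm(60), 10, 6)
  y <- rep(c(-1, 1), 5)
  fit <- fit_pls(X, y, n_components = 3)
  v <- vip_scores(fit)
  expect_equal(mean(v$vip^2), 1, tolerance = 1e-12)

  # direct evaluation of the formula from stored quantities
  ss <- fit$y_loadings^2 * fit$score_ss
  p <- 6
  vip_bf <- vapply(1:p, function(j)
    sqrt(p * sum(ss * fit$x_weights[j, ]^2) / sum(ss)), numeric(1))
  expect_equal(v$vip, vip_bf, tolerance = 1e-10)

  # a single informative column dominates and is selected
  X2 <- matrix(rnorm(120, sd = 0.1), 20, 6)
  X2[, 4] <- rep(c(2, -2), 10)
  f2 <- fit_pls(X2, rep(c(1, -1), 10), 2)
  v2 <- vip_scores(f2)
  expect_equal(which.max(v2$vip), 4L)
  expect_true(v2$selected[4])
})

test_that("confusion metrics follow the standard definitions", {
  perfect <- confusion_metrics(c("deceased", "survivor"),
                               c("deceased", "survivor"))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  pred <- c(rep("deceased", 20), rep("survivor", 6),   # truth deceased
            rep("deceased", 25), rep("survivor", 55))  # truth survivor
  truth <- c(rep("deceased", 26), rep("survivor", 80))
  m <- confusion_metrics(pred, truth)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(20, 6, 25, 55))
  expect_equal(round(m$sensitivity, 3), 0.769)
  expect_equal(round(m$specificity, 3), 0.688)
  expect_equal(round(m$accuracy, 3), 0.708)

  allneg <- confusion_metrics(rep("survivor", 4),
                              c("deceased", "deceased", "survivor", "survivor"))
  expect_equal(allneg$sensitivity, 0)
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("LOOCV yields perfect accuracy on tight separated clusters and runs at n = 4", {
  sep <- make_separable_matrix(n_per_class = 6, p = 5, shift = 8)
  cv <- loocv(sep$X, sep$y, n_components = 2)
  expect_equal(cv$metrics$accuracy, 1)
  expect_length(cv$predicted, 12)

  tiny <- make_separable_matrix(n_per_class = 2, p = 3, shift = 8)
  cv4 <- loocv(tiny$X, tiny$y, n_components = 1)
  expect_length(cv4$predicted, 4)
  expect_error(loocv(sep$X[1:2, ], sep$y[1:2], 1), "n >= 3")
})

test_that("LOOCV accuracy is at chance under label permutation", {
  set.seed(11)
  X <- matrix(rnorm(60 * 10), 60, 10)
  acc <- replicate(50, {
    y <- sample(rep(c("deceased", "survivor"), 30))
    loocv(X, y, n_components = 3)$metrics$accuracy
  })
  expect_gt(mean(acc), 0.4)
  expect_lt(mean(acc), 0.6)
})

test_that("LOOCV accuracy does not exceed resubstitution accuracy on average", {
  diffs <- vapply(1:20, function(s) {
    fc <- make_feature_cohort(n = 40, seed = 100 + s, cv = 0.6)
    fit <- fit_pls(fc$X, fc$cohort$true_class, n_components = 5)
    resub <- confusion_metrics(predict(fit, fc$X, type = "class"),
                               fc$cohort$true_class)$accuracy
    cv <- loocv(fc$X, fc$cohort$true_class, n_components = 5)$metrics$accuracy
    resub - cv
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("the printed performance triple pins a unique confusion matrix", {
  rec <- reconstruct_confusion(76.9, 68.8, 70.8, n_pos = 26, n_neg = 80)
  expect_equal(nrow(rec), 1L)
  expect_equal(as.integer(rec[1, ]), c(20L, 6L, 55L, 25L))
})
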