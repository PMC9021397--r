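test_that("ppm calibration shifts the detected peak onto the reference", {
  grid <- seq(4.9, 5.6, by = 0.001)
  peaked <- function(center) new_spectrum(grid, nmrisk:::lorentzian(grid, center, 0.004))

  already <- calibrate_ppm(peaked(5.24))
  expect_equal(attr(already, "shift"), 0)
  expect_equal(already$ppm, grid)

  off <- calibrate_ppm(peaked(5.26))
  expect_equal(attr(off, "shift"), -0.02, tolerance = 1e-9)
  expect_equal(off$ppm[which.max(off$intensity)], 5.24, tolerance = 1e-9)

  flat <- new_spectrum(grid, rep(1, length(grid)))
  expect_error(calibrate_ppm(flat), "no peak found in window")
  expect_error(calibrate_ppm(peaked(5.24), reference_ppm = 9),
               "does not cover window")
})

test_that("binning arithmetic: counts, rectangle areas, frozen retained-bin count", {
  grid <- seq(0.1, 10.1, by = 0.005)
  const <- new_spectrum(grid, rep(1, length(grid)))

  b5 <- bin_spectrum(const, range = c(0.2, 0.3), exclusions = list())
  expect_length(b5, 5)

  b_all <- bin_spectrum(const, exclusions = list())
  expect_length(b_all, 490)
  expect_equal(unname(as.numeric(b_all)), rep(0.02, 490), tolerance = 1e-12)

  # regression: the default exclusions retain 434 of 490 bins under the
  # positive-overlap drop convention
  b_ex <- bin_spectrum(const)
  expect_length(b_ex, 434)
  starts <- attr(b_ex, "bin_starts")
  for (ex in default_exclusions())
    expect_false(any(starts < ex[2] - 1e-9 & starts + 0.02 > ex[1] + 1e-9))

  expect_error(bin_spectrum(const, bin_width = 0), "bin_width")
  expect_warning(bin_spectrum(const, exclusions = list(c(11, 12))),
                 "outside the binning range")
})

test_that("binning is invariant to the ppm axis direction", {
  s <- generate_spectrum("survivor", noise_sd = 0, seed = 4)
  rev_s <- new_spectrum(rev(s$ppm), rev(s$intensity), s$sample_id)
  expect_equal(as.numeric(bin_spectrum(s)), as.numeric(bin_spectrum(rev_s)),
               tolerance = 1e-12)
})

test_that("PQN quotients behave per construction on hand-computable cases", {
  bm <- function(values) {
    structure(list(values = values, bin_starts = seq_len(ncol(values)),
                   bin_width = 0.02, excluded_regions = list(),
                   normalization = "raw", quotients = NULL, reference = NULL),
              class = "binned_matrix")
  }
  # sample equal to / multiple of the reference
  v <- rbind(a = c(1, 2, 4), b = c(1, 2, 4) * 3)
  n <- pqn_normalize(bm(v))
  # reference = element-wise median = 2x the base row
  expect_equal(unname(n$quotients), c(0.5, 1.5))
  expect_equal(unname(n$values[1, ]), unname(n$values[2, ]))

  # spec'd toy: A = (1,2,4), B = (2,2,2); reference (1.5, 2, 3)
  v2 <- rbind(A = c(1, 2, 4), B = c(2, 2, 2))
  n2 <- pqn_normalize(bm(v2))
  expect_equal(unname(n2$quotients), c(1, 1))
  expect_equal(n2$values, v2)

  expect_error(pqn_normalize(bm(rbind(a = c(0, 0, 0), b = c(1, 1, 1)))),
               "all-zero sample")
  expect_error(pqn_normalize(bm(v[1, , drop = FALSE])), "at least 2 samples")
})

test_that("PQN is idempotent and removes simulated dilution", {
  cfg <- sim_config(n_patients = 24, dilution_cv = 0.3, noise_sd = 0, seed = 6)
  cohort <- generate_cohort(cfg)
  # dilution isolated as the only variance source (no biological variation,
  # no class effects, no noise)
  peaks <- dcm_peak_library(effect_scale = 0, cv = 0)
  spectra <- generate_spectra(cohort, cfg, peaks)
  norm <- pqn_normalize(bin_spectra(spectra))
  expect_gt(cor(cohort$dilution, norm$quotients), 0.99)
  renorm <- pqn_normalize(norm)
  expect_lt(max(abs(renorm$quotients - 1)), 1e-10)
  expect_equal(renorm$values, norm$values, tolerance = 1e-12)
})

test_that("PCA scores match the SVD decomposition and behave on degenerate input", {
  set.seed(8)
  X <- matrix(rnorm(40), 8, 5)
  mine <- pca_scores(X, 4)
  orc <- prcomp(X, center = TRUE, scale. = FALSE)
  for (k in 1:4)
    expect_lt(min(max(abs(mine$scores[, k] - orc$x[, k])),
                  max(abs(mine$scores[, k] + orc$x[, k]))), 1e-8)
  expect_equal(mine$explained_variance,
               (orc$sdev^2 / sum(orc$sdev^2))[1:4], tolerance = 1e-10)
  expect_lte(sum(mine$explained_variance), 1 + 1e-12)
  expect_true(all(diff(mine$explained_variance) <= 1e-12))
  # scores orthogonal
  g <- crossprod(mine$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)

  # perfect line in bin space: one component carries all variance
  t <- rnorm(10)
  line <- outer(t, c(1, 2, 3))
  expect_equal(pca_scores(line, 1)$explained_variance, 1, tolerance = 1e-12)

  expect_error(pca_scores(X, 0), "n_components")
  expect_error(pca_scores(X, 8), "n_components")
})

test_that("spectra and binned matrices round-trip through their text formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_patients = 4, seed = 13)
  cohort <- generate_cohort(cfg)
  spectra <- generate_spectra(cohort, cfg,
                              ppm_grid = seq(0.2, 10, by = 0.01))
  write_spectra(spectra, file.path(dir, "spec"))
  back <- read_spectra(file.path(dir, "spec"))
  expect_equal(names(back), cohort$patient_id)
  expect_equal(back[[2]]$intensity, spectra[[2]]$intensity, tolerance = 1e-6)

  norm <- pqn_normalize(bin_spectra(spectra))
  path <- file.path(dir, "binned.csv")
  write_binned_matrix(norm, path)
  back2 <- read_binned_matrix(path)
  expect_equal(back2$values, norm$values, tolerance = 1e-12)
  expect_equal(back2$normalization, "pqn")
  expect_equal(unname(back2$quotients), unname(norm$quotients),
               tolerance = 1e-12)
  expect_equal(back2$bin_starts, norm$bin_starts)
})
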