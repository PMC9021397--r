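# Shared fixtures, all generated in code.

# Two well-separated Gaussian clusters in p dimensions.
make_separable_matrix <- function(n_per_class = 10, p = 8, shift = 4,
                                  seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  X[seq_len(n_per_class), 1:2] <- X[seq_len(n_per_class), 1:2] + shift
  y <- rep(c("deceased", "survivor"), each = n_per_class)
  rownames(X) <- sprintf("S%02d", seq_len(nrow(X)))
  list(X = X, y = y)
}

# Small synthetic cohort + log-scale feature matrix for classifier tests.
make_feature_cohort <- function(n = 60, prop = 0.5, seed = 5,
                                effects = dcm_feature_effects(), cv = 0.2) {
  cfg <- sim_config(n_patients = n, prop_deceased = prop, seed = seed)
  cohort <- generate_cohort(cfg)
  ft <- generate_feature_table(cohort, effects, cv = cv, seed = seed)
  list(cohort = cohort, X = log(as.matrix(ft[, -1])), config = cfg)
}

# Two-group exponential survival data with administrative censoring.
make_survival_data <- function(n = 300, hr = 3, baseline = 0.08,
                               censor = 10, seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, baseline * exp(log(hr) * g))
  list(time = pmin(t, censor), event = as.integer(t <= censor), group = g)
}
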