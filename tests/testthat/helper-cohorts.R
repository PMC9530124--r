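# Shared fixtures, all generated in code.

# single-point grid for fast deterministic refits
fast_grid <- function(nrounds = 100, depth = 3) {
  data.frame(max_depth = depth, eta = 0.1, nrounds = nrounds, min_child_weight = 1)
}

# cohort dominated by non-linear structure: a U-shaped analyte and an
# age-by-exposure interaction, plus a saturating threshold
nonlinear_spec <- function(n_subjects, seed) {
  cohort_spec(
    n_subjects = n_subjects,
    effects = list(
      planted_effect("age", "monotone", weight = 0.5),
      planted_effect("urate", "u_shape", weight = 1.2, v0 = 5, curvature = 0.8),
      planted_effect("lead", "monotone", weight = 0.3),
      planted_effect("lead", "interaction", weight = -0.8, partner = "age"),
      planted_effect("urine_albumin", "threshold", weight = 0.9, v_t = 5.8)
    ),
    n_noise_features = 4, missingness = 0.05,
    beta0 = stats::qlogis(0.05), seed = seed)
}

# label mechanism with no feature dependence at a given baseline rate
null_spec <- function(n_subjects, rate = 0.1, seed = 1) {
  cohort_spec(n_subjects = n_subjects, effects = list(),
              n_noise_features = 5, missingness = 0,
              beta0 = stats::qlogis(rate), seed = seed)
}

# small random model for attribution tests: d features, few shallow trees,
# optionally with missing values sprinkled in
random_small_model <- function(seed, n = 60, d = 3, depth = 3, nrounds = 4,
                               with_na = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", seq_len(d))))
  if (with_na) x[sample(length(x), round(0.1 * length(x)))] <- NA
  lin <- ifelse(is.na(x[, 1]), 0, x[, 1])
  y <- rbinom(n, 1, plogis(lin))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  ft <- feature_table(as.data.frame(x),
                      stats::setNames(rep("laboratory", d), colnames(x)))
  model <- fit_gbt(ft, y, grid = fast_grid(nrounds, depth), seed = seed)
  list(model = model, ft = ft, x = x, y = y)
}

# brute-force all-pairs AUROC used as the evaluation oracle
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
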