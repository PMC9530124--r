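make_redundancy_fixture <- function(n = 4000, seed = 60) {
  set.seed(seed)
  x1 <- rnorm(n, 5, 1)
  data.frame(
    x1 = x1,
    x1_mono = exp(x1 / 2),           # exact monotone transform of x1
    noise = rnorm(n, 5, 1),
    y = rbinom(n, 1, plogis(1.2 * (x1 - 5) - 1.5))
  )
}

test_that("supervised distance hits its structural limits", {
  d <- make_redundancy_fixture()
  expect_gte(supervised_r2(d$x1, d$x1, d$y), 0.99)
  expect_lt(supervised_distance(d$x1, d$x1, d$y), 0.01)
  expect_lt(supervised_distance(d$x1, d$x1_mono, d$y), 0.1)
  expect_gt(supervised_distance(d$x1, d$noise, d$y), 0.9)
  expect_lt(supervised_r2(d$x1, d$noise, d$y), 0.1)
})

test_that("the R-squared arithmetic clips at zero and handles constants", {
  p <- c(0.1, 0.5, 0.9, 0.3)
  # anti-informative reproduction: residual mean square exceeds the variance
  p_bad <- c(0.9, 0.1, 0.1, 0.9)
  expect_identical(treemort:::r2_from_predictions(p, p_bad), 0)
  # constant prediction vector: defined as 0, not an exception
  expect_identical(treemort:::r2_from_predictions(rep(0.4, 4), p), 0)
  # perfect reproduction
  expect_equal(treemort:::r2_from_predictions(p, p), 1)
})

test_that("the distance matrix matches one-at-a-time calls, symmetric, bounded", {
  d <- make_redundancy_fixture(n = 800)
  ft <- feature_table(d[c("x1", "x1_mono", "noise")],
                      c(x1 = "laboratory", x1_mono = "laboratory", noise = "laboratory"))
  dm <- supervised_distance_matrix(ft, d$y, keep_predictions = TRUE)
  D <- dm$distance
  expect_equal(max(abs(D - t(D))), 0)
  expect_identical(unname(diag(D)), rep(0, 3))
  expect_true(all(D >= 0 - 1e-9 & D <= 1 + 1e-9))
  for (pair in list(c("x1", "x1_mono"), c("x1", "noise"))) {
    direct <- supervised_distance(d[[pair[1]]], d[[pair[2]]], d$y)
    expect_equal(D[pair[1], pair[2]], direct, tolerance = 1e-10)
  }
  # Eq. arithmetic re-derived from the stored prediction vectors
  P <- dm$predictions$P; PIJ <- dm$predictions$PIJ
  for (i in dm$features) for (j in setdiff(dm$features, i)) {
    ratio <- mean((P[[i]] - PIJ[[paste0(i, "||", j)]])^2) /
      mean((P[[i]] - mean(P[[i]]))^2)
    expect_identical(dm$r2[i, j], max(0, 1 - ratio))
  }
})

test_that("complete-linkage clustering respects k and isolates planted groups", {
  cohort <- generate_cohort(default_cohort_spec(2500, seed = 61))
  y <- cohort$labels[, "5y"]
  members <- c("arm_circumference", "bmi", "waist", "weight")
  feats <- sort(c(members, "urate", "rdw", "noise_01"))
  dm <- supervised_distance_matrix(cohort$table, y, features = feats)
  expect_identical(unname(cluster_features(dm, k = length(feats))$assignment),
                   seq_along(feats))
  expect_identical(unname(unique(cluster_features(dm, k = 1)$assignment)), 1L)
  cl <- cluster_features(dm, k = 4)
  expect_length(unique(cl$assignment[members]), 1)
  expect_identical(sum(cl$assignment == cl$assignment[[members[1]]]), 4L)
  # linkage heights are non-decreasing
  expect_true(!is.unsorted(cl$hclust$height))
  expect_error(cluster_features(dm, k = 0), "k must lie")
})

test_that("supervised-distance selection prunes redundancy and protects age/sex", {
  cohort <- generate_cohort(default_cohort_spec(2500, n_noise_features = 4, seed = 62))
  y <- cohort$labels[, "5y"]
  sp <- split_cohort(cohort$table, seed = 62)
  sel <- sd_feature_selection(cohort$table, y, sp, step = 5, n_boot = 50,
                              shap_n = 400, seed = 62)
  members <- c("arm_circumference", "bmi", "waist", "weight")
  for (s in sel$sets) expect_true(all(c("age", "sex") %in% s))
  # redundancy collapses after the first pruning iteration
  for (s in sel$sets[-1]) expect_lte(sum(s %in% members), 1)
  # shrinking feature sets trend towards larger minimum distances
  expect_lt(cor(sel$trajectory$size, sel$trajectory$min_distance,
                method = "spearman"), 0)
  expect_true(all(diff(sel$trajectory$size) < 0))
})

test_that("selection rescues the importance credit split between near-copies", {
  set.seed(63)
  spec <- cohort_spec(
    3000,
    effects = list(planted_effect("age", "monotone", weight = 0.8),
                   planted_effect("sig_a", "monotone", weight = 1.0)),
    redundancy_groups = list(redundancy_group("sig", c("sig_a", "sig_b"),
                                              noise_sd = 0.02)),
    n_noise_features = 2, missingness = 0, seed = 63)
  cohort <- generate_cohort(spec)
  y <- cohort$labels[, "5y"]
  sp <- split_cohort(cohort$table, seed = 63)
  full <- fit_gbt(ft_subset(cohort$table, sp$train), y[sp$train],
                  grid = fast_grid(100), seed = 63)
  imp_full <- shap_importance(shap_values(full, ft_subset(cohort$table, sp$train)))
  copies <- imp_full$importance[match(c("sig_a", "sig_b"), imp_full$feature)]

  sel <- sd_feature_selection(cohort$table, y, sp, step = 2, n_boot = 50,
                              shap_n = 800, seed = 63)
  final <- sel$sets[[length(sel$sets)]]
  expect_identical(sum(final %in% c("sig_a", "sig_b")), 1L)
  kept <- intersect(final, c("sig_a", "sig_b"))
  refit <- fit_gbt(ft_subset(cohort$table, rows = sp$train, features = final),
                   y[sp$train], grid = fast_grid(100), seed = 63)
  imp_refit <- shap_importance(shap_values(
    refit, ft_subset(cohort$table, rows = sp$train, features = final)))
  expect_gt(imp_refit$importance[imp_refit$feature == kept], max(copies))
})
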