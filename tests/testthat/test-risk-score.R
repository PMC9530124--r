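test_that("tiers admit the right feature roles", {
  ft <- generate_cohort(default_cohort_spec(200, seed = 80))$table
  roles <- ft$roles
  pub <- feature_tier(ft, "public")
  expect_false(any(roles[pub$features] == "laboratory"))
  pro <- feature_tier(ft, "professional")
  expect_setequal(unique(unname(roles[pro$features])), c("demographic", "laboratory"))
  expect_setequal(feature_tier(ft, "all")$features, names(roles))
  pan <- feature_tier(ft, "panel", panel = c("urate", "rdw"))
  expect_setequal(pan$features, c("age", "sex", "urate", "rdw"))
  expect_error(feature_tier(ft, "panel"), "requires a feature list")
  expect_error(feature_tier(ft, "panel", panel = "not_there"), "absent")
})

test_that("importance-based RFE retains planted signal at the recorded size", {
  cohort <- generate_cohort(cohort_spec(
    3500,
    effects = list(planted_effect("age", "monotone", weight = 1.0),
                   planted_effect("s1", "monotone", weight = 0.9),
                   planted_effect("s2", "monotone", weight = -0.9),
                   planted_effect("s3", "u_shape", weight = 1.2, v0 = 5),
                   planted_effect("s4", "threshold", weight = 1.0, v_t = 5.5)),
    n_noise_features = 12, missingness = 0, seed = 81))
  y <- cohort$labels[, "5y"]
  sp <- split_cohort(cohort$table, seed = 81)
  rfe <- rfe_by_importance(cohort$table, y, sp, step = 5, min_size = 7,
                           grid = fast_grid(120), n_boot = 50, shap_n = 600,
                           seed = 81)
  expect_true(all(diff(rfe$trajectory$size) <= -1))
  final <- rfe$sets[[length(rfe$sets)]][1:7]
  expect_true(all(c("age", "s1", "s2", "s3", "s4") %in% final))
  expect_error(rfe_by_importance(cohort$table, y, sp, min_size = 100), "exceeds")
})

test_that("risk scores respect the tier, embed their model, and rank tiers by signal", {
  cohort <- generate_cohort(default_cohort_spec(2500, seed = 82))
  y <- cohort$labels[, "5y"]
  ft <- cohort$table
  sp <- split_cohort(ft, seed = 82)
  rs_all <- build_risk_score(ft, y, sp, tier = feature_tier(ft, "all"), size = 8,
                             grid = fast_grid(120), n_boot = 50, shap_n = 500,
                             seed = 82)
  rs_pub <- build_risk_score(ft, y, sp, tier = feature_tier(ft, "public"), size = 6,
                             grid = fast_grid(120), n_boot = 50, shap_n = 500,
                             seed = 82)
  expect_identical(rs_all$size, 8L)
  expect_false(any(ft$roles[rs_pub$features] == "laboratory"))
  test_ft <- ft_subset(ft, sp$test)
  expect_identical(predict_risk(rs_all, test_ft), predict_risk(rs_all$model, test_ft))
  # laboratory features carry planted signal, so the full tier must win
  expect_gt(rs_all$evaluations$overall$auroc, rs_pub$evaluations$overall$auroc)
  # per-sex strata were evaluated
  expect_true(any(grepl("^sex=", names(rs_all$evaluations))))
})

test_that("temporal validation matches random-split accuracy on stationary cohorts", {
  cohort <- generate_cohort(default_cohort_spec(4000, seed = 83))
  y <- cohort$labels[, "5y"]
  ft <- cohort$table
  sp_t <- split_cohort(ft, mode = "temporal", cutoff = 6)
  rs <- build_risk_score(ft, y, sp_t, size = 8, grid = fast_grid(120),
                         n_boot = 50, shap_n = 500, seed = 83)
  later <- ft_subset(ft, sp_t$test)
  tv <- temporal_validate(rs, later, y[sp_t$test], n_boot = 50, seed = 83)

  sp_r <- split_cohort(ft, seed = 83)
  rs_r <- build_risk_score(ft, y, sp_r, size = 8, grid = fast_grid(120),
                           n_boot = 50, shap_n = 500, seed = 83)
  expect_lt(abs(tv$auroc - rs_r$evaluations$overall$auroc), 0.03)

  # adversarial later-cycle mechanism: flipped labels score below chance
  tv_flip <- temporal_validate(rs, later, 1L - y[sp_t$test], n_boot = 50, seed = 83)
  expect_lt(tv_flip$auroc, 0.5)

  # overlapping cycles are rejected
  expect_error(temporal_validate(rs, ft, y), "overlap")
})

test_that("individual explanations reconstruct the risk score exactly", {
  cohort <- generate_cohort(default_cohort_spec(2000, seed = 84))
  y <- cohort$labels[, "5y"]
  ft <- cohort$table
  sp <- split_cohort(ft, seed = 84)
  rs <- build_risk_score(ft, y, sp, size = 8, grid = fast_grid(100),
                         n_boot = 50, shap_n = 500, seed = 84)
  subj <- ft$data[sp$test[1], ]
  ex <- explain_individual(rs, subj)
  expect_equal(ex$base + sum(ex$contributions$contribution), ex$risk,
               tolerance = 1e-10)
  expect_equal(ex$risk, as.numeric(predict_risk(rs, subj)), tolerance = 1e-12)
  # permuting the subject's columns leaves the explanation unchanged
  ex2 <- explain_individual(rs, subj[, rev(names(subj))])
  expect_identical(ex$contributions, ex2$contributions)
})

test_that("extreme exposures dominate their own explanations", {
  cohort <- generate_cohort(default_cohort_spec(2500, seed = 85))
  y <- cohort$labels[, "5y"]
  ft <- cohort$table
  sp <- split_cohort(ft, seed = 85)
  rs <- build_risk_score(ft, y, sp, size = 8, grid = fast_grid(120),
                         n_boot = 50, shap_n = 500, seed = 85)
  stopifnot("rdw" %in% rs$features)
  test_rdw <- ft$data$rdw[sp$test]
  extreme <- sp$test[!is.na(test_rdw) & test_rdw > quantile(test_rdw, 0.95, na.rm = TRUE)]
  extreme <- head(extreme, 12)
  hits <- vapply(extreme, function(i) {
    ex <- explain_individual(rs, ft$data[i, ])
    # age dominates most explanations by design; rdw must lead among the rest
    top_nonage <- setdiff(ex$contributions$feature, "age")[1]
    identical(top_nonage, "rdw")
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
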