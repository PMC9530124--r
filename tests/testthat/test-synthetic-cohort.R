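test_that("null mechanism calibrates to the baseline rate and labels nest", {
  spec <- null_spec(10000, rate = 0.1, seed = 11)
  cohort <- generate_cohort(spec)
  p <- plogis(spec$beta0 + spec$horizon_shifts)
  for (h in seq_along(p)) {
    rate <- mean(cohort$labels[, h])
    expect_lt(abs(rate - p[h]), 3 * sqrt(p[h] * (1 - p[h]) / 10000))
  }
  # one latent uniform draw: death by a short horizon implies death later
  expect_true(all(cohort$labels[, "1y"] <= cohort$labels[, "5y"]))
  expect_true(all(cohort$labels[, "5y"] <= cohort$labels[, "10y"]))
})

test_that("a strong monotone effect orders event probability across deciles", {
  spec <- cohort_spec(8000, effects = list(planted_effect("rdw", "monotone", weight = 2)),
                      missingness = 0, seed = 3)
  cohort <- generate_cohort(spec)
  v <- cohort$truth$features_complete$rdw
  dec <- cut(v, quantile(v, 0:10 / 10), include.lowest = TRUE)
  rates <- tapply(cohort$truth$prob[, "5y"], dec, mean)
  expect_true(all(diff(rates) > 0))
})

test_that("generation is reproducible and seed-sensitive", {
  spec <- default_cohort_spec(400, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$table$data, b$table$data)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$prob, b$truth$prob)
  c2 <- generate_cohort(spec, seed = 8)
  expect_false(identical(a$table$data, c2$table$data))
})

test_that("true_risk honors the planted shape contracts", {
  spec <- cohort_spec(
    100,
    effects = list(planted_effect("urate", "u_shape", weight = 1, v0 = 5),
                   planted_effect("urine_albumin", "threshold", weight = 1, v_t = 5.8)),
    missingness = 0, seed = 1)
  # u-shape contribution vanishes exactly at the optimum (albumin at its
  # ramp start contributes nothing either)
  expect_equal(true_risk(spec, data.frame(urate = 5, urine_albumin = 1)),
               plogis(spec$beta0 + 0), tolerance = 1e-12)
  # threshold contribution is constant above the knot
  r1 <- true_risk(spec, data.frame(urate = 5, urine_albumin = 5.8))
  r2 <- true_risk(spec, data.frame(urate = 5, urine_albumin = 15.8))
  expect_identical(r1, r2)
  # consistency with probabilities stored at generation
  cohort <- generate_cohort(default_cohort_spec(300, seed = 2))
  expect_equal(true_risk(cohort$spec, cohort$truth$features_complete, horizon = 5),
               unname(cohort$truth$prob[, "5y"]), tolerance = 1e-12)
  expect_error(true_risk(spec, data.frame(urate = 5)), "missing")
})

test_that("planted reference intervals cover the right regions", {
  cohort <- generate_cohort(default_cohort_spec(4000, seed = 5))
  truth <- cohort$truth
  # u-shape: optimal interval straddles the planted optimum
  ri_u <- make_reference_intervals(truth, "urate")
  expect_lt(ri_u$optimal$low, 4.6)
  expect_gt(ri_u$optimal$high, 4.6)
  # monotone increasing: the mis-set interval reaches the upper range end
  ri_m <- make_reference_intervals(truth, "rdw")
  curve <- true_relative_risk(truth, "rdw")
  expect_gte(ri_m$misset$high, curve$value[which.max(curve$rr)])
  # threshold: the mis-set interval contains the plateau's risk maximum
  ri_t <- make_reference_intervals(truth, "urine_albumin")
  curve_t <- true_relative_risk(truth, "urine_albumin")
  argmax <- curve_t$value[which.max(curve_t$rr)]
  expect_true(ri_t$misset$low <= argmax && argmax <= ri_t$misset$high)
  # both intervals are ordered
  for (ri in list(ri_u, ri_m, ri_t)) {
    expect_lt(ri$optimal$low, ri$optimal$high)
    expect_lt(ri$misset$low, ri$misset$high)
  }
  # features without an effect are rejected
  expect_error(make_reference_intervals(truth, "noise_01"), "no planted effect")
})

test_that("redundancy-group members are noisy monotone copies of one latent", {
  spec <- cohort_spec(
    3000,
    redundancy_groups = list(redundancy_group("size", c("a", "b", "c"), noise_sd = 0.1)),
    effects = list(planted_effect("a", "monotone", weight = 0.5)),
    missingness = 0, seed = 9)
  cohort <- generate_cohort(spec)
  d <- cohort$table$data
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_gt(cor(d[[pair[1]]], d[[pair[2]]], method = "spearman"), 0.8)
  expect_identical(unname(cohort$truth$group_assign[c("a", "b", "c")]),
                   rep("size", 3))
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(100, missingness = 1), "missingness")
  expect_error(planted_effect("x", "monotone", weight = Inf), "finite")
  expect_error(cohort_spec(100, redundancy_groups = list(
    redundancy_group("g1", c("a", "b")), redundancy_group("g2", c("b", "c")))),
    "more than one redundancy group")
  expect_error(cohort_spec(100, effects = list(
    planted_effect("x", "u_shape", weight = 1, v0 = 99))), "outside")
  expect_error(planted_effect("x", "interaction", weight = 1, partner = "x"),
               "must differ")
  expect_error(redundancy_group("g", "only_one"), ">= 2 members")
})

test_that("missingness is MCAR at the requested rate and spares demographics", {
  cohort <- generate_cohort(default_cohort_spec(5000, missingness = 0.2, seed = 4))
  d <- cohort$table$data
  roles <- cohort$table$roles
  expect_false(anyNA(d$age)); expect_false(anyNA(d$sex))
  lab_miss <- vapply(d[names(roles)[roles != "demographic"]],
                     function(v) mean(is.na(v)), numeric(1))
  expect_true(all(abs(lab_miss - 0.2) < 0.03))
})
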