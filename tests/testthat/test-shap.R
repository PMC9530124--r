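test_that("attributions match the brute-force Shapley oracle on small ensembles", {
  set.seed(50)
  worst <- 0
  for (rep in 1:12) {
    fit <- random_small_model(rep + 100, n = 60, d = sample(2:4, 1),
                              depth = sample(2:3, 1), nrounds = sample(3:5, 1))
    bg <- as.data.frame(fit$x[1:25, , drop = FALSE])
    att <- shap_values(fit$model, fit$ft, background = bg)
    for (i in sample(nrow(fit$x), 2)) {
      oracle <- brute_force_shapley(fit$model,
                                    as.data.frame(fit$x)[i, , drop = FALSE],
                                    background = bg)
      worst <- max(worst, max(abs(att$phi[i, ] - oracle)))
    }
    expect_lt(max(abs(att$base + rowSums(att$phi) - att$margin)), 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("the oracle rejects enumeration beyond 12 features", {
  set.seed(51)
  d <- 13
  x <- matrix(rnorm(40 * d), 40, d, dimnames = list(NULL, paste0("f", 1:d)))
  y <- rbinom(40, 1, plogis(x[, 1])); y[1:2] <- 0:1
  ft <- feature_table(as.data.frame(x), setNames(rep("laboratory", d), colnames(x)))
  m <- fit_gbt(ft, y, grid = fast_grid(3))
  expect_error(brute_force_shapley(m, as.data.frame(x)[1, ]), "12 features")
})

test_that("a model with no splits attributes nothing", {
  set.seed(52)
  x <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  y <- rbinom(80, 1, 0.4); y[1:2] <- 0:1
  ft <- feature_table(x, c(x1 = "laboratory", x2 = "laboratory"))
  # a huge min_child_weight forbids any split: constant model
  m <- fit_gbt(ft, y, grid = data.frame(max_depth = 3, eta = 0.3, nrounds = 4,
                                        min_child_weight = 1e6))
  att <- shap_values(m, ft)
  expect_equal(max(abs(att$phi)), 0)
  expect_equal(att$margin, rep(att$base, 80))
})

test_that("a feature the trees never split on gets zero attribution", {
  set.seed(53)
  x <- data.frame(x1 = rnorm(120), dummy = 1)   # constant: never split on
  y <- as.integer(x$x1 > 0)
  ft <- feature_table(x, c(x1 = "laboratory", dummy = "laboratory"))
  m <- fit_gbt(ft, y, grid = fast_grid(10))
  att <- shap_values(m, ft)
  expect_equal(max(abs(att$phi[, "dummy"])), 0)
  oracle <- brute_force_shapley(m, x[1, ])
  expect_equal(unname(oracle["dummy"]), 0)
})

test_that("interaction tensors are symmetric, row-sum to phi, and vanish for additive models", {
  fit <- random_small_model(54, n = 120, d = 3, depth = 3, nrounds = 8)
  att <- shap_interactions(fit$model, fit$ft$data[1:15, ])
  ia <- att$interactions
  for (i in seq_len(dim(ia)[3])) {
    expect_equal(ia[, , i], t(ia[, , i]), tolerance = 1e-10)
    expect_equal(rowSums(ia[, , i]), att$phi[i, ], tolerance = 1e-6)
  }
  # depth-1 trees are additive by construction: off-diagonals exactly zero
  add <- fit_gbt(fit$ft, fit$y, grid = fast_grid(12, depth = 1))
  att1 <- shap_interactions(add, fit$ft$data[1:10, ])
  off <- att1$interactions
  for (i in seq_len(dim(off)[3])) diag(off[, , i]) <- 0
  expect_equal(max(abs(off)), 0)
})

test_that("a planted interaction dominates the off-diagonal interaction mass", {
  cohort <- generate_cohort(nonlinear_spec(2500, seed = 55))
  y <- cohort$labels[, "5y"]
  sp <- split_cohort(cohort$table, seed = 55)
  m <- fit_gbt(ft_subset(cohort$table, sp$train), y[sp$train],
               grid = fast_grid(150), seed = 55)
  set.seed(55)
  sub <- sort(sample(sp$train, 300))
  att <- shap_interactions(m, ft_subset(cohort$table, rows = sub))
  mass <- apply(abs(att$interactions), c(1, 2), mean)
  diag(mass) <- 0
  top <- which(mass == max(mass), arr.ind = TRUE)[1, ]
  expect_setequal(c(rownames(mass)[top[1]], colnames(mass)[top[2]]),
                  c("age", "lead"))
})

test_that("importance ranks by mean absolute attribution with lexicographic ties", {
  phi <- cbind(b = c(1, -1), a = c(-1, 1), c = c(0, 0))
  att <- structure(list(phi = phi, base = 0, margin = c(0, 0),
                        features = colnames(phi), n_background = 1),
                   class = "attribution_set")
  imp <- shap_importance(att)
  expect_identical(imp$feature, c("a", "b", "c"))   # tie a/b broken by name
  expect_identical(imp$feature[3], "c")             # zero attribution last
  att2 <- att; att2$phi <- phi[c(2, 1), ]
  expect_identical(shap_importance(att2)$feature, imp$feature)
})

test_that("strengthening a feature's role increases its mean absolute attribution", {
  set.seed(56)
  n <- 1200
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  ft <- feature_table(x, c(x1 = "laboratory", x2 = "laboratory"))
  y_weak <- rbinom(n, 1, plogis(0.3 * x$x1 + x$x2))
  y_strong <- rbinom(n, 1, plogis(1.5 * x$x1 + x$x2))
  m_weak <- fit_gbt(ft, y_weak, grid = fast_grid(60))
  m_strong <- fit_gbt(ft, y_strong, grid = fast_grid(60))
  i_weak <- shap_importance(shap_values(m_weak, ft))
  i_strong <- shap_importance(shap_values(m_strong, ft))
  expect_gt(i_strong$importance[i_strong$feature == "x1"],
            i_weak$importance[i_weak$feature == "x1"])
})

test_that("ranking comparison reproduces exact hypergeometric inference", {
  u <- sprintf("f%02d", 1:51)
  b <- c(u[1:14], u[21:26], u[15:20], u[27:51])
  cmp <- compare_rankings(u, b, universe = u, k = 20)
  expect_identical(cmp$overlap, 14L)
  expect_equal(round(cmp$fisher_p, 4), 4e-04)

  # identity
  cmp_id <- compare_rankings(u, u, universe = u, k = 20)
  expect_identical(cmp_id$overlap, 20L)
  expect_equal(cmp_id$spearman_rho, 1)

  # enumeration oracle on a random draw
  set.seed(57)
  u2 <- sprintf("g%02d", 1:40)
  b2 <- sample(u2)
  k <- 10
  cmp2 <- compare_rankings(u2, b2, universe = u2, k = k)
  m <- 40
  probs <- dhyper(0:k, k, m - k, k)
  p_oracle <- sum(probs[probs <= probs[cmp2$overlap + 1] * (1 + 1e-7)])
  expect_equal(cmp2$fisher_p, p_oracle, tolerance = 1e-9)

  expect_error(compare_rankings(u2, b2, universe = u2, k = 41), "exceeds")
})
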