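# Mortality classifiers: gradient-boosted trees with grid search + 5-fold CV,
# and a regularized logistic baseline on median-imputed features.

#' Split a cohort into training and testing sets
#'
#' @param ft a [feature_table()].
#' @param mode `"random"` (default 80/20 by seeded draw) or `"temporal"`
#'   (all cycles `<= cutoff` train, later cycles test).
#' @param prop training proportion for random splits.
#' @param cutoff cycle cutoff for temporal splits.
#' @param seed seed for the random mode.
#' @return A list of class `cohort_split` with integer index vectors `train`
#'   and `test` (disjoint and exhaustive).
#' @export
split_cohort <- function(ft, mode = c("random", "temporal"), prop = 0.8,
                         cutoff = NULL, seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(ft$data)
  if (mode == "random") {
    n_train <- round(prop * n)
    train <- with_seed(seed, sort(sample.int(n, n_train)))
  } else {
    if (is.null(ft$cycle)) stop_tm("temporal split requires a cycle column")
    if (is.null(cutoff)) stop_tm("temporal split requires a cutoff")
    rng <- range(ft$cycle)
    if (cutoff < rng[1] || cutoff >= rng[2])
      stop_tm(sprintf("cutoff %s outside the usable cycle range [%d, %d)",
                      format(cutoff), rng[1], rng[2]))
    train <- which(ft$cycle <= cutoff)
  }
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 mode = mode, seed = seed, cutoff = cutoff),
            class = "cohort_split")
}

#' Default hyperparameter grid for [fit_gbt()]
#'
#' @return data.frame of candidate hyperparameter combinations.
#' @export
default_gbt_grid <- function() {
  expand.grid(max_depth = c(3, 6), eta = c(0.1, 0.05),
              nrounds = c(100, 500), min_child_weight = c(1, 10),
              KEEP.OUT.ATTRS = FALSE)
}

# stratified fold assignment, seeded
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

xgb_params <- function(row, nthread = 1L) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       max_depth = as.integer(row$max_depth), eta = row$eta,
       min_child_weight = row$min_child_weight, nthread = nthread)
}

#' Fit a gradient-boosted-tree mortality classifier
#'
#' Selects hyperparameters by grid search with stratified k-fold
#' cross-validated AUROC (ties broken by grid order), then refits on the full
#' training data. Missing feature values are passed natively to the learner.
#'
#' @param ft a [feature_table()] (training subjects only).
#' @param labels binary 0/1 outcome vector.
#' @param grid data.frame with columns `max_depth`, `eta`, `nrounds`,
#'   `min_child_weight`; defaults to [default_gbt_grid()].
#' @param folds number of cross-validation folds.
#' @param seed seed controlling fold assignment and the learner.
#' @return An object of class `c("gbt_model", "mortality_model")` holding the
#'   fitted booster, its feature list, the chosen hyperparameters, and the
#'   full tuning record.
#' @export
fit_gbt <- function(ft, labels, grid = default_gbt_grid(), folds = 5, seed = 1L) {
  labels <- as.integer(labels)
  x <- ft_matrix(ft)
  if (nrow(x) != length(labels)) stop_tm("labels must match the table's rows")
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop_tm("labels must contain both classes")
  all_missing <- names(which(colSums(!is.na(x)) == 0))
  if (length(all_missing))
    stop_tm("features with all values missing: ", paste(all_missing, collapse = ", "))
  if (!is.data.frame(grid) || nrow(grid) == 0) stop_tm("grid must be non-empty")

  tuning <- grid
  tuning$cv_auroc <- NA_real_
  if (nrow(grid) > 1L) {
    fold <- stratified_folds(labels, folds, seed)
    for (g in seq_len(nrow(grid))) {
      aucs <- numeric(folds)
      for (k in seq_len(folds)) {
        tr <- fold != k
        dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = labels[tr], missing = NA)
        bst <- with_seed(seed + k, xgboost::xgb.train(
          params = xgb_params(grid[g, ]), data = dtr,
          nrounds = grid$nrounds[g], verbose = 0))
        p <- predict(bst, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], missing = NA))
        aucs[k] <- auroc(p, labels[!tr])
      }
      tuning$cv_auroc[g] <- mean(aucs)
    }
    best <- which.max(tuning$cv_auroc)      # which.max keeps the first tie
  } else best <- 1L

  dtrain <- xgboost::xgb.DMatrix(x, label = labels, missing = NA)
  booster <- with_seed(seed, xgboost::xgb.train(
    params = xgb_params(grid[best, ]), data = dtrain,
    nrounds = grid$nrounds[best], verbose = 0))

  bg_idx <- with_seed(seed, sample.int(nrow(x), min(nrow(x), 100L)))
  structure(
    list(booster = booster, features = colnames(x),
         params = grid[best, , drop = FALSE], tuning = tuning,
         train_x = x, train_labels = labels,
         background_idx = sort(bg_idx), seed = seed,
         cache = new.env(parent = emptyenv())),
    class = c("gbt_model", "mortality_model"))
}

#' @export
print.gbt_model <- function(x, ...) {
  cat(sprintf("Gradient-boosted-tree mortality model (%d features, %d training subjects)\n",
              length(x$features), nrow(x$train_x)))
  p <- x$params
  cat(sprintf("  depth=%d eta=%g nrounds=%d min_child_weight=%g\n",
              p$max_depth, p$eta, p$nrounds, p$min_child_weight))
  invisible(x)
}

model_matrix_for <- function(model, newdata) {
  data <- if (inherits(newdata, "feature_table")) newdata$data else as.data.frame(newdata)
  missing_f <- setdiff(model$features, names(data))
  if (length(missing_f))
    stop_tm("newdata lacks model features: ", paste(missing_f, collapse = ", "))
  m <- as.matrix(data[, model$features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Predict event probability
#'
#' @param model a fitted `mortality_model` (GBT or linear baseline).
#' @param newdata a [feature_table()] or data.frame holding the model's
#'   features.
#' @return Vector of probabilities in `[0, 1]` (the sigmoid of the model's
#'   margin).
#' @export
predict_risk <- function(model, newdata) UseMethod("predict_risk")

#' @export
predict_risk.gbt_model <- function(model, newdata) {
  m <- model_matrix_for(model, newdata)
  predict(model$booster, xgboost::xgb.DMatrix(m, missing = NA))
}

# margin (log-odds) prediction from the booster itself
predict_margin <- function(model, newdata) {
  m <- model_matrix_for(model, newdata)
  predict(model$booster, xgboost::xgb.DMatrix(m, missing = NA), outputmargin = TRUE)
}

#' Fit the regularized logistic baseline
#'
#' Linear comparison model: features are median-imputed (linear models cannot
#' take missing values natively) and fit with ridge-penalized logistic
#' regression, the penalty chosen by cross-validation.
#'
#' @param ft a [feature_table()] (training subjects only).
#' @param labels binary 0/1 outcome vector.
#' @param seed seed for the cross-validation folds.
#' @return An object of class `c("linear_model", "mortality_model")` with the
#'   same predict interface as [fit_gbt()].
#' @export
fit_linear_baseline <- function(ft, labels, seed = 1L) {
  labels <- as.integer(labels)
  x <- ft_matrix(ft)
  if (length(unique(labels)) < 2L) stop_tm("labels must contain both classes")
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  if (anyNA(med)) stop_tm("features with all values missing: ",
                          paste(colnames(x)[is.na(med)], collapse = ", "))
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  fit <- with_seed(seed, glmnet::cv.glmnet(x, labels, family = "binomial",
                                           alpha = 0, nfolds = 5))
  structure(list(fit = fit, medians = med, features = colnames(x), seed = seed),
            class = c("linear_model", "mortality_model"))
}

#' @export
predict_risk.linear_model <- function(model, newdata) {
  m <- model_matrix_for(model, newdata)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- model$medians[j]
  as.numeric(predict(model$fit, newx = m, s = "lambda.min", type = "response"))
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("Ridge logistic baseline (%d features, lambda.min = %.4g)\n",
              length(x$features), x$fit$lambda.min))
  invisible(x)
}
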