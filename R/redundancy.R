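# Supervised distance: a task-aware feature-redundancy metric.
#
# For features i and j, a univariate tree model of the label from i yields
# Prediction_i; a second univariate tree model of Prediction_i from j yields
# Prediction_i^j. Then
#   supervised R2(i,j) = max(0, 1 - mean((P_i - P_i^j)^2 / var(P_i)))
#   supervised distance(i,j) = max(1 - R2(i,j), 1 - R2(j,i))
# so 0 means the features carry the same information about the outcome and
# 1 means none shared.

# Univariate boosted-tree fit at the learner's default hyperparameters
# (eta 0.3, depth 6, min_child_weight 1); the boosting-round count, which the
# library leaves to the user, is fixed at 50 and recorded in the result.
UNIVARIATE_NROUNDS <- 50L

univariate_prediction <- function(x, y, objective) {
  m <- matrix(as.double(x), ncol = 1, dimnames = list(NULL, "x"))
  dm <- xgboost::xgb.DMatrix(m, label = y, missing = NA)
  bst <- xgboost::xgb.train(
    params = list(objective = objective, nthread = 1L,
                  eval_metric = if (objective == "binary:logistic") "logloss" else "rmse"),
    data = dm, nrounds = UNIVARIATE_NROUNDS, verbose = 0)
  predict(bst, dm)
}

# Eq. arithmetic on stored prediction vectors; var is the population variance
# so a constant predictor gives exactly 0 (a feature carrying no label
# information is not redundant with anything).
r2_from_predictions <- function(p_i, p_ij) {
  v <- mean((p_i - mean(p_i))^2)
  if (v < 1e-12) return(0)
  max(0, 1 - mean((p_i - p_ij)^2) / v)
}

#' Supervised R-squared between two features
#'
#' How well feature `j` can reproduce the univariate model output of feature
#' `i` for the given prediction task. Asymmetric; see
#' [supervised_distance()] for the symmetrized metric.
#'
#' @param xi,xj numeric feature vectors.
#' @param labels binary 0/1 outcomes.
#' @param train optional index vector restricting the computation to
#'   training subjects.
#' @param space output space of the label model: `"probability"` (default)
#'   or `"margin"`.
#' @return Supervised R-squared in `[0, 1]`.
#' @export
supervised_r2 <- function(xi, xj, labels, train = NULL, space = c("probability", "margin")) {
  space <- match.arg(space)
  train <- train %||% seq_along(labels)
  p_i <- univariate_prediction(xi[train], as.integer(labels)[train], "binary:logistic")
  if (space == "margin") p_i <- stats::qlogis(pmin(pmax(p_i, 1e-12), 1 - 1e-12))
  p_ij <- univariate_prediction(xj[train], p_i, "reg:squarederror")
  r2_from_predictions(p_i, p_ij)
}

#' Supervised distance between two features
#'
#' `max(1 - R2(i,j), 1 - R2(j,i))`: symmetric, roughly in `[0, 1]`;
#' 0 means perfectly redundant for the task, 1 means not redundant.
#'
#' @inheritParams supervised_r2
#' @return Supervised distance.
#' @export
supervised_distance <- function(xi, xj, labels, train = NULL,
                                space = c("probability", "margin")) {
  space <- match.arg(space)
  max(1 - supervised_r2(xi, xj, labels, train, space),
      1 - supervised_r2(xj, xi, labels, train, space))
}

# internal: cached machinery reused by the matrix and the selection loop.
# cache env holds P[[feature]] and d[["i||j"]].
sd_cache <- function() new.env(parent = emptyenv())

cached_prediction <- function(cache, ft, labels, train, feature, space) {
  key <- paste0("P::", feature)
  if (is.null(cache[[key]])) {
    p <- univariate_prediction(ft$data[[feature]][train], as.integer(labels)[train],
                               "binary:logistic")
    if (space == "margin") p <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
    cache[[key]] <- p
  }
  cache[[key]]
}

cached_r2 <- function(cache, ft, labels, train, i, j, space) {
  key <- paste0("R2::", i, "||", j)
  if (is.null(cache[[key]])) {
    p_i <- cached_prediction(cache, ft, labels, train, i, space)
    p_ij <- univariate_prediction(ft$data[[j]][train], p_i, "reg:squarederror")
    cache[[paste0("PIJ::", i, "||", j)]] <- p_ij
    cache[[key]] <- r2_from_predictions(p_i, p_ij)
  }
  cache[[key]]
}

cached_distance <- function(cache, ft, labels, train, i, j, space) {
  if (i == j) return(0)
  key <- paste0("D::", paste(sort(c(i, j)), collapse = "||"))
  if (is.null(cache[[key]]))
    cache[[key]] <- max(1 - cached_r2(cache, ft, labels, train, i, j, space),
                        1 - cached_r2(cache, ft, labels, train, j, i, space))
  cache[[key]]
}

#' Supervised-distance matrix over all feature pairs
#'
#' Univariate label-model outputs are computed once per feature and reused
#' across pairs, which gives values identical to one-at-a-time
#' [supervised_distance()] calls.
#'
#' @param ft a [feature_table()].
#' @param labels binary 0/1 outcomes.
#' @param train optional training index vector (distances are computed on
#'   the training split only).
#' @param features subset of features (default all).
#' @param space `"probability"` or `"margin"`.
#' @param keep_predictions store the underlying `Prediction_i` and
#'   `Prediction_i^j` vectors for arithmetic re-derivation.
#' @param cache optional cache environment (see [sd_feature_selection()]).
#' @return An object of class `sd_matrix`: list with `distance` (symmetric,
#'   zero-diagonal matrix in `[0, 1]`), `r2` (asymmetric supervised
#'   R-squared matrix), `features`, and optionally `predictions`.
#' @export
supervised_distance_matrix <- function(ft, labels, train = NULL, features = NULL,
                                       space = c("probability", "margin"),
                                       keep_predictions = FALSE, cache = NULL) {
  space <- match.arg(space)
  features <- features %||% names(ft$data)
  if (length(features) < 2L) stop_tm("need at least 2 features")
  train <- train %||% seq_len(nrow(ft$data))
  cache <- cache %||% sd_cache()
  p <- length(features)
  D <- matrix(0, p, p, dimnames = list(features, features))
  R2 <- matrix(1, p, p, dimnames = list(features, features))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    R2[i, j] <- cached_r2(cache, ft, labels, train, features[i], features[j], space)
  }
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    D[i, j] <- D[j, i] <- max(1 - R2[i, j], 1 - R2[j, i])
  }
  out <- structure(list(distance = D, r2 = R2, features = features, space = space),
                   class = "sd_matrix")
  if (keep_predictions) {
    P <- lapply(features, function(f) cache[[paste0("P::", f)]])
    names(P) <- features
    PIJ <- list()
    for (i in features) for (j in setdiff(features, i))
      PIJ[[paste0(i, "||", j)]] <- cache[[paste0("PIJ::", i, "||", j)]]
    out$predictions <- list(P = P, PIJ = PIJ)
  }
  out
}

#' @export
print.sd_matrix <- function(x, ...) {
  cat(sprintf("Supervised-distance matrix over %d features (%s space)\n",
              length(x$features), x$space))
  off <- x$distance[upper.tri(x$distance)]
  cat(sprintf("  distances: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Complete-linkage feature clustering on a supervised-distance matrix
#'
#' Merges in each step the two clusters whose merger has the smallest
#' diameter. Features are processed in lexicographic name order so ties
#' break deterministically.
#'
#' @param dmat an `sd_matrix` (or a plain symmetric distance matrix).
#' @param k requested number of flat clusters, `1 <= k <=` feature count.
#' @return An object of class `feature_clustering`: list with `hclust`, `k`,
#'   and `assignment` (named integer vector partitioning the features).
#' @export
cluster_features <- function(dmat, k) {
  D <- if (inherits(dmat, "sd_matrix")) dmat$distance else as.matrix(dmat)
  feats <- sort(rownames(D))
  if (k < 1 || k > length(feats)) stop_tm("k must lie in [1, number of features]")
  D <- D[feats, feats]
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  assignment <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, k = k, assignment = assignment),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("Complete-linkage feature clustering: %d features into %d clusters\n",
              length(x$assignment), x$k))
  invisible(x)
}

min_pairwise_distance <- function(cache, ft, labels, train, features, space) {
  if (length(features) < 2L) return(NA_real_)
  best <- Inf
  for (i in seq_along(features)[-length(features)])
    for (j in (i + 1):length(features))
      best <- min(best, cached_distance(cache, ft, labels, train,
                                        features[i], features[j], space))
  best
}

#' Supervised-distance-based recursive feature selection
#'
#' Iteratively: fit a tree model on the current feature set, rank features by
#' mean absolute Shapley attribution, cluster the non-protected features by
#' supervised distance into `step` fewer groups, keep the most important
#' member of each cluster, re-add the protected features, and refit. Each
#' iteration records the feature set, its held-out bootstrap AUROC, and the
#' minimum pairwise supervised distance within the set. Iteration stops once
#' the non-protected features form a single cluster. Clustering is rerun on
#' the surviving set each iteration, but pairwise distance entries are
#' cached and never recomputed.
#'
#' @param ft a [feature_table()].
#' @param labels binary 0/1 outcomes.
#' @param split a [split_cohort()] partition.
#' @param keep features always retained (default `c("age", "sex")`).
#' @param step features removed per iteration (default 5).
#' @param grid single-row hyperparameter grid for the refits.
#' @param n_boot bootstrap replicates for the held-out AUROC.
#' @param space supervised-distance output space.
#' @param shap_n foreground subsample size for the importance ranking.
#' @param seed seed.
#' @return An object of class `sd_selection`: list with `trajectory`
#'   (data.frame of size, AUROC, CI, minimum supervised distance) and `sets`
#'   (the recorded feature sets).
#' @export
sd_feature_selection <- function(ft, labels, split, keep = c("age", "sex"),
                                 step = 5, grid = NULL, n_boot = 200,
                                 space = c("probability", "margin"),
                                 shap_n = 1000, seed = 1L) {
  space <- match.arg(space)
  grid <- grid %||% data.frame(max_depth = 3, eta = 0.1, nrounds = 150,
                               min_child_weight = 1)
  missing_keep <- setdiff(keep, names(ft$data))
  if (length(missing_keep))
    stop_tm("always-keep features absent: ", paste(missing_keep, collapse = ", "))
  cache <- sd_cache()
  train <- split$train; test <- split$test
  current <- names(ft$data)
  sets <- list(); traj <- list(); it <- 0L

  repeat {
    it <- it + 1L
    ft_cur <- ft_subset(ft, features = current)
    model <- fit_gbt(ft_subset(ft_cur, rows = train), labels[train],
                     grid = grid, seed = seed)
    scores <- predict_risk(model, ft_subset(ft_cur, rows = test))
    ev <- evaluate_auroc(scores, labels[test], n_boot = n_boot, seed = seed)
    fg <- with_seed(seed, sample.int(length(train), min(length(train), shap_n)))
    imp <- shap_importance(shap_values(model, ft_subset(ft_cur, rows = train[fg])))
    md <- min_pairwise_distance(cache, ft, labels, train, current, space)

    sets[[it]] <- current
    traj[[it]] <- data.frame(size = length(current), auroc = ev$auroc,
                             ci_lo = ev$ci[1], ci_hi = ev$ci[2],
                             min_distance = md)

    nonkept <- setdiff(current, keep)
    if (length(nonkept) <= 1L) break
    k_target <- max(1L, length(nonkept) - step)
    dm <- supervised_distance_matrix(ft, labels, train = train,
                                     features = nonkept, space = space,
                                     cache = cache)
    cl <- cluster_features(dm, k_target)
    imp_lookup <- stats::setNames(imp$importance, imp$feature)
    picks <- vapply(split(names(cl$assignment), cl$assignment), function(members) {
      members[order(-imp_lookup[members], members)][1]
    }, character(1))
    current <- c(intersect(names(ft$data), keep), unname(picks))
    if (k_target == 1L) {
      # record the final, single-cluster set before stopping
      ft_cur <- ft_subset(ft, features = current)
      model <- fit_gbt(ft_subset(ft_cur, rows = train), labels[train],
                       grid = grid, seed = seed)
      scores <- predict_risk(model, ft_subset(ft_cur, rows = test))
      ev <- evaluate_auroc(scores, labels[test], n_boot = n_boot, seed = seed)
      md <- min_pairwise_distance(cache, ft, labels, train, current, space)
      it <- it + 1L
      sets[[it]] <- current
      traj[[it]] <- data.frame(size = length(current), auroc = ev$auroc,
                               ci_lo = ev$ci[1], ci_hi = ev$ci[2],
                               min_distance = md)
      break
    }
  }
  structure(list(trajectory = do.call(rbind, traj), sets = sets, keep = keep),
            class = "sd_selection")
}

#' @export
print.sd_selection <- function(x, ...) {
  cat("Supervised-distance feature selection trajectory\n")
  print(x$trajectory, row.names = FALSE)
  invisible(x)
}
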