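# Shapley attributions for tree-ensemble mortality models.
#
# shap_values() computes exact interventional Shapley values with respect to
# a background sample, by the leaf-wise conjunction-game decomposition in
# src/treeshap.cpp. brute_force_shapley() is the independent oracle: direct
# enumeration over feature coalitions with the same background-average value
# function, evaluated through the booster's own predict method.

# Parse the booster into flat node arrays (0-based indices), cached on the
# model. Leaf values live in the dump's Gain column.
parse_trees <- function(model) {
  if (!is.null(model$cache$trees)) return(model$cache$trees)
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
  idx <- stats::setNames(seq_len(nrow(dt)) - 1L, dt$ID)
  is_leaf <- dt$Feature == "Leaf"
  fidx <- match(dt$Feature, model$features) - 1L
  fidx[is_leaf] <- -1L
  if (anyNA(fidx)) stop_tm("tree dump references unknown features")
  to_idx <- function(ids) { out <- unname(idx[ids]); out[is.na(out)] <- -1L; out }
  cfg <- xgboost::xgb.config(model$booster)
  base_margin <- stats::qlogis(as.numeric(cfg$learner$learner_model_param$base_score))
  trees <- list(
    feature = as.integer(fidx),
    split = ifelse(is_leaf, 0, dt$Split),
    yes = to_idx(dt$Yes), no = to_idx(dt$No), missing = to_idx(dt$Missing),
    value = ifelse(is_leaf, dt$Gain, 0),
    roots = unname(idx[dt$ID[dt$Node == 0]]),
    base_margin = base_margin)
  model$cache$trees <- trees
  trees
}

# double-precision margin from the parsed trees (leaf sum + base margin)
tree_margin <- function(model, newdata) {
  tr <- parse_trees(model)
  m <- model_matrix_for(model, newdata)
  cpp_tree_margin(m, tr$feature, tr$split, tr$yes, tr$no, tr$missing,
                  tr$value, tr$roots) + tr$base_margin
}

default_background <- function(model) {
  model$train_x[model$background_idx, , drop = FALSE]
}

#' Interventional Shapley attributions
#'
#' Computes per-subject additive attributions in margin (log-odds) space for
#' a fitted gradient-boosted-tree model: the exact Shapley values of the
#' interventional coalition game whose value function replaces out-of-
#' coalition features with background-sample values and averages the model
#' margin. Attributions satisfy the additivity contract
#' `base + sum(phi) = margin` in double precision.
#'
#' @param model a [fit_gbt()] model.
#' @param newdata a [feature_table()] or data.frame of foreground subjects.
#' @param background background matrix/data.frame (defaults to a fixed
#'   100-row subsample of the training data chosen at fit time).
#' @param interactions if `TRUE`, also compute the pairwise Shapley
#'   interaction tensor (diagonal = main effects; rows sum to `phi`).
#' @return An object of class `attribution_set`: list with `phi` (subjects x
#'   features), `base` (expected margin over the background), `margin`
#'   (per-subject model margin), optional `interactions` (features x
#'   features x subjects array), and `features`.
#' @export
shap_values <- function(model, newdata, background = NULL, interactions = FALSE) {
  if (!inherits(model, "gbt_model")) stop_tm("shap_values requires a gbt_model")
  x <- model_matrix_for(model, newdata)
  bg <- if (is.null(background)) default_background(model)
        else model_matrix_for(model, background)
  tr <- parse_trees(model)
  res <- cpp_treeshap(x, bg, tr$feature, tr$split, tr$yes, tr$no, tr$missing,
                      tr$value, tr$roots, isTRUE(interactions))
  phi <- res$phi
  colnames(phi) <- model$features
  out <- structure(
    list(phi = phi,
         base = mean(res$margin_b) + tr$base_margin,
         margin = as.numeric(res$margin_x) + tr$base_margin,
         features = model$features,
         n_background = nrow(bg)),
    class = "attribution_set")
  if (isTRUE(interactions)) {
    inter <- res$interactions
    dimnames(inter) <- list(model$features, model$features, NULL)
    out$interactions <- inter
  }
  out
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf("Shapley attributions: %d subjects x %d features (log-odds space)\n",
              nrow(x$phi), ncol(x$phi)))
  cat(sprintf("  base value %.4f; background n = %d; interactions: %s\n",
              x$base, x$n_background, !is.null(x$interactions)))
  err <- max(abs(x$base + rowSums(x$phi) - x$margin))
  cat(sprintf("  max additivity error %.2e\n", err))
  invisible(x)
}

#' Brute-force Shapley oracle
#'
#' Exact Shapley values by enumeration over all `2^d` feature coalitions,
#' with the coalition value estimated by the interventional convention: out-
#' of-coalition features take background-sample values and the booster's own
#' margin predictions are averaged. Limited to 12 features. Deterministic
#' given the background; independent of the leaf-wise path used by
#' [shap_values()].
#'
#' @param model a [fit_gbt()] model.
#' @param x a single subject (one-row data.frame or named vector).
#' @param background background matrix/data.frame (default as in
#'   [shap_values()]).
#' @return Named attribution vector in margin space.
#' @export
brute_force_shapley <- function(model, x, background = NULL) {
  if (is.numeric(x) && !is.null(names(x))) x <- as.data.frame(as.list(x))
  xm <- model_matrix_for(model, x)
  if (nrow(xm) != 1L) stop_tm("x must be a single subject")
  bg <- if (is.null(background)) default_background(model)
        else model_matrix_for(model, background)
  d <- ncol(xm)
  if (d > 12L) stop_tm("brute-force enumeration is limited to 12 features")
  nb <- nrow(bg)
  n_masks <- 2^d

  hyb <- matrix(NA_real_, n_masks * nb, d, dimnames = list(NULL, model$features))
  for (mask in 0:(n_masks - 1)) {
    block <- bg
    in_S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) != 0L)
    for (j in in_S) block[, j] <- xm[1, j]
    hyb[(mask * nb + 1):((mask + 1) * nb), ] <- block
  }
  margins <- predict(model$booster, xgboost::xgb.DMatrix(hyb, missing = NA),
                     outputmargin = TRUE)
  vals <- vapply(0:(n_masks - 1), function(mask)
    mean(margins[(mask * nb + 1):((mask + 1) * nb)]), numeric(1))

  wt <- vapply(0:(d - 1L), function(s)
    exp(lfactorial(s) + lfactorial(d - 1L - s) - lfactorial(d)), numeric(1))
  phi <- numeric(d)
  sizes <- vapply(0:(n_masks - 1), function(mask) sum(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) != 0L), integer(1))
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(n_masks - 1), bit) == 0L) - 1L
    for (mask in without) {
      s <- sizes[mask + 1L]
      phi[i] <- phi[i] + wt[s + 1L] * (vals[bitwOr(mask, bit) + 1L] - vals[mask + 1L])
    }
  }
  stats::setNames(phi, model$features)
}

#' Pairwise Shapley interaction tensor
#'
#' Convenience wrapper around [shap_values()] with `interactions = TRUE`.
#' The returned tensor is symmetric in its first two dimensions, its diagonal
#' holds main effects, and each subject's row sums reproduce `phi`.
#'
#' @inheritParams shap_values
#' @return The `attribution_set` with its `interactions` array filled.
#' @export
shap_interactions <- function(model, newdata, background = NULL) {
  shap_values(model, newdata, background = background, interactions = TRUE)
}

#' Global importance ranking by mean absolute attribution
#'
#' @param attr an `attribution_set`.
#' @return An object of class `importance_ranking`: data.frame with columns
#'   `feature`, `importance` (mean |phi|), `rank`, ordered by decreasing
#'   importance, ties broken lexicographically by feature name.
#' @export
shap_importance <- function(attr) {
  stopifnot(inherits(attr, "attribution_set"))
  if (nrow(attr$phi) == 0L) stop_tm("empty attribution set")
  imp <- colMeans(abs(attr$phi))
  ord <- order(-imp, names(imp))
  out <- data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
                    rank = seq_along(imp), row.names = NULL)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

ranking_features <- function(x) {
  if (inherits(x, "importance_ranking")) return(x$feature)
  if (is.character(x)) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(names(sort(-x)))
  stop_tm("rankings must be importance_ranking objects, ordered character vectors, or named numerics")
}

#' Compare two importance rankings over a shared feature universe
#'
#' Restricts both rankings to the shared universe, counts the overlap of
#' their top-k sets, tests it with a two-sided Fisher exact test on the 2x2
#' in/out-of-top-k table (exact hypergeometric enumeration, via
#' [stats::fisher.test()]), and reports the Spearman rank correlation of the
#' two orderings over the universe.
#'
#' @param a,b rankings: `importance_ranking` objects, character vectors
#'   ordered most-to-least important, or named importance vectors.
#' @param universe character vector of shared features (default: the
#'   intersection of the two rankings).
#' @param k top-set size (default 20).
#' @return List of class `ranking_comparison` with `overlap`, `fisher_p`,
#'   `spearman_rho`, `k`, `universe_size`, `top_a`, `top_b`.
#' @export
#' @examples
#' # 51-feature universe, top-20 sets sharing 14 members
#' u <- sprintf("f%02d", 1:51)
#' a <- u
#' b <- c(u[1:14], u[21:26], u[15:20], u[27:51])
#' compare_rankings(a, b, universe = u, k = 20)$fisher_p
compare_rankings <- function(a, b, universe = NULL, k = 20) {
  fa <- ranking_features(a); fb <- ranking_features(b)
  universe <- universe %||% intersect(fa, fb)
  if (k > length(universe)) stop_tm("k exceeds the size of the shared universe")
  ra <- fa[fa %in% universe]; rb <- fb[fb %in% universe]
  if (!setequal(ra, universe) || !setequal(rb, universe))
    stop_tm("both rankings must cover the shared universe")
  top_a <- ra[seq_len(k)]; top_b <- rb[seq_len(k)]
  overlap <- length(intersect(top_a, top_b))
  m <- length(universe)
  tab <- matrix(c(overlap, k - overlap, k - overlap, m - 2 * k + overlap), 2, 2)
  fisher_p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  pos_a <- match(universe, ra); pos_b <- match(universe, rb)
  rho <- stats::cor(pos_a, pos_b, method = "spearman")
  structure(list(overlap = overlap, fisher_p = fisher_p, spearman_rho = rho,
                 k = k, universe_size = m, top_a = top_a, top_b = top_b),
            class = "ranking_comparison")
}

#' @export
print.ranking_comparison <- function(x, ...) {
  cat(sprintf("Top-%d overlap: %d of %d shared features\n", x$k, x$overlap, x$universe_size))
  cat(sprintf("  Fisher exact p = %.4g; Spearman rho = %.4f\n", x$fisher_p, x$spearman_rho))
  invisible(x)
}
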