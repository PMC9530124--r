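# Tiered, cost-aware mortality risk scores: SHAP-importance recursive
# feature elimination, bootstrap/sex-stratified/temporal evaluation, and
# individualized explanations in probability space.

#' Feature tier for cost-aware risk scores
#'
#' Tiers encode who can collect the features: the general public can supply
#' demographic, examination and questionnaire features but not laboratory
#' results; medical professionals work from demographics plus laboratory
#' features; a common-test-panel tier is a configurable named feature list
#' (plus demographics); `all` admits everything.
#'
#' @param ft a [feature_table()] (supplies the feature roles).
#' @param tier `"public"`, `"professional"`, `"panel"`, or `"all"`.
#' @param panel character vector of laboratory features for the panel tier.
#' @return An object of class `feature_tier` with the admissible feature
#'   set.
#' @export
feature_tier <- function(ft, tier = c("all", "public", "professional", "panel"),
                         panel = NULL) {
  tier <- match.arg(tier)
  roles <- ft$roles
  feats <- names(roles)
  admissible <- switch(tier,
    all = feats,
    public = feats[roles %in% c("demographic", "examination", "questionnaire")],
    professional = feats[roles %in% c("demographic", "laboratory")],
    panel = {
      if (is.null(panel)) stop_tm("panel tier requires a feature list")
      missing_p <- setdiff(panel, feats)
      if (length(missing_p)) stop_tm("panel features absent: ", paste(missing_p, collapse = ", "))
      union(feats[roles == "demographic"], panel)
    })
  if (!length(admissible)) stop_tm("tier admits no features")
  structure(list(tier = tier, features = admissible, panel = panel),
            class = "feature_tier")
}

#' Recursive feature elimination by mean absolute Shapley importance
#'
#' Starting from a tier's full admissible pool, iteratively refits the tree
#' model, ranks features by mean absolute attribution, drops the `step`
#' least-important features, and records size, feature list and held-out
#' bootstrap AUROC at every visited size. Deterministic given the seed.
#'
#' @param ft a [feature_table()].
#' @param labels binary 0/1 outcomes.
#' @param split a [split_cohort()] partition.
#' @param tier a [feature_tier()] (default: all features).
#' @param step features removed per iteration (default 5).
#' @param min_size smallest model size recorded (default 2).
#' @param grid single-row hyperparameter grid used for the refits.
#' @param n_boot bootstrap replicates per evaluation.
#' @param shap_n foreground subsample size for the importance ranking.
#' @param seed seed.
#' @return An object of class `rfe_trajectory`: list with `trajectory`
#'   (data.frame of `size`, `auroc`, `ci_lo`, `ci_hi`) and `sets` (feature
#'   lists, ordered most- to least-important).
#' @export
rfe_by_importance <- function(ft, labels, split, tier = NULL, step = 5,
                              min_size = 2, grid = NULL, n_boot = 200,
                              shap_n = 1000, seed = 1L) {
  tier <- tier %||% feature_tier(ft, "all")
  grid <- grid %||% data.frame(max_depth = 3, eta = 0.1, nrounds = 150,
                               min_child_weight = 1)
  pool <- intersect(names(ft$data), tier$features)
  if (!length(pool)) stop_tm("tier admits no features present in the table")
  if (min_size > length(pool)) stop_tm("requested size exceeds the tier's feature pool")
  train <- split$train; test <- split$test
  current <- pool
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
    sets[[it]] <- imp$feature          # ordered by importance
    traj[[it]] <- data.frame(size = length(current), auroc = ev$auroc,
                             ci_lo = ev$ci[1], ci_hi = ev$ci[2])
    n_drop <- min(step, length(current) - min_size)
    if (n_drop <= 0L) break
    current <- imp$feature[seq_len(length(current) - n_drop)]
  }
  structure(list(trajectory = do.call(rbind, traj), sets = sets,
                 tier = tier$tier), class = "rfe_trajectory")
}

#' @export
print.rfe_trajectory <- function(x, ...) {
  cat(sprintf("Importance-based RFE trajectory (tier: %s)\n", x$tier))
  print(x$trajectory, row.names = FALSE)
  invisible(x)
}

#' Build a tiered mortality risk score
#'
#' Runs importance-based recursive feature elimination within the tier down
#' to the requested size, fits the final model on the selected features, and
#' attaches held-out bootstrap evaluations overall and per sex stratum. The
#' risk score of a subject is the model's predicted event probability.
#'
#' @inheritParams rfe_by_importance
#' @param size number of features in the final score.
#' @param sex_feature name of the sex column used for stratified evaluation
#'   (skipped if absent from the table or excluded by the tier).
#' @return An object of class `risk_score_model`: list with `model`,
#'   `features` (ordered by importance), `tier`, `size`, `evaluations`
#'   (named list of [evaluate_auroc()] results), and `train_cycles`.
#' @export
build_risk_score <- function(ft, labels, split, tier = NULL, size = 20,
                             step = 5, grid = NULL, n_boot = 200,
                             shap_n = 1000, sex_feature = "sex", seed = 1L) {
  tier <- tier %||% feature_tier(ft, "all")
  pool <- intersect(names(ft$data), tier$features)
  if (size > length(pool)) stop_tm("requested size exceeds the tier's feature pool")
  rfe <- rfe_by_importance(ft, labels, split, tier = tier, step = step,
                           min_size = size, grid = grid, n_boot = n_boot,
                           shap_n = shap_n, seed = seed)
  last <- rfe$sets[[length(rfe$sets)]]
  selected <- last[seq_len(min(size, length(last)))]
  grid <- grid %||% data.frame(max_depth = 3, eta = 0.1, nrounds = 150,
                               min_child_weight = 1)
  train <- split$train; test <- split$test
  ft_sel <- ft_subset(ft, features = selected)
  model <- fit_gbt(ft_subset(ft_sel, rows = train), labels[train],
                   grid = grid, seed = seed)
  scores <- predict_risk(model, ft_subset(ft_sel, rows = test))
  evaluations <- list(
    overall = evaluate_auroc(scores, labels[test], n_boot = n_boot, seed = seed))
  if (sex_feature %in% names(ft$data)) {
    sex <- ft$data[[sex_feature]][test]
    for (s in sort(unique(sex[!is.na(sex)]))) {
      lab <- paste0(sex_feature, "=", s)
      evaluations[[lab]] <- tryCatch(
        evaluate_auroc(scores, labels[test], n_boot = n_boot, seed = seed,
                       stratum = !is.na(sex) & sex == s, stratum_label = lab),
        error = function(e) NULL)
    }
  }
  structure(list(model = model, features = selected, tier = tier$tier,
                 size = length(selected), evaluations = evaluations,
                 rfe = rfe$trajectory,
                 train_cycles = if (!is.null(ft$cycle)) ft$cycle[train]),
            class = "risk_score_model")
}

#' @export
print.risk_score_model <- function(x, ...) {
  cat(sprintf("Mortality risk score: tier '%s', %d features\n", x$tier, x$size))
  for (nm in names(x$evaluations))
    if (!is.null(x$evaluations[[nm]])) {
      cat(sprintf("  %-12s ", nm)); print(x$evaluations[[nm]])
    }
  invisible(x)
}

#' Predicted risk score
#'
#' @param model a [build_risk_score()] model.
#' @param newdata evaluation data.
#' @return Event probabilities (the risk scores).
#' @export
predict_risk.risk_score_model <- function(model, newdata) {
  predict_risk(model$model, newdata)
}

#' Temporal validation of a risk score
#'
#' Evaluates the score on subjects from enrollment cycles strictly later
#' than every training cycle; overlapping cycles are rejected.
#'
#' @param score a [build_risk_score()] model.
#' @param ft validation [feature_table()] (later cycles only).
#' @param labels binary 0/1 outcomes for the validation subjects.
#' @param n_boot bootstrap replicates.
#' @param seed seed.
#' @return An [evaluate_auroc()] result.
#' @export
temporal_validate <- function(score, ft, labels, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(score, "risk_score_model"))
  if (is.null(ft$cycle) || is.null(score$train_cycles))
    stop_tm("temporal validation requires cycle information on both sides")
  if (min(ft$cycle) <= max(score$train_cycles))
    stop_tm("validation cycles overlap the training cycles")
  scores <- predict_risk(score, ft)
  evaluate_auroc(scores, labels, n_boot = n_boot, seed = seed,
                 stratum_label = "temporal")
}

#' Individualized risk-score explanation
#'
#' Explains one subject's risk score in probability space: the base value is
#' the mean predicted risk over the model's training set, and the log-odds
#' Shapley attributions are rescaled proportionally so that base value plus
#' contributions reconstructs the subject's risk score exactly (a documented
#' approximation of probability-space attribution; when the attributions sum
#' to zero the contributions are all zero).
#'
#' @param score a [build_risk_score()] model.
#' @param subject a one-row data.frame (or named vector) with the model's
#'   features.
#' @return An object of class `individual_explanation`: list with `risk`
#'   (probability), `base` (mean training risk), and `contributions`
#'   (data.frame of feature, value, contribution, sorted by absolute
#'   contribution).
#' @export
explain_individual <- function(score, subject) {
  stopifnot(inherits(score, "risk_score_model"))
  if (is.numeric(subject) && !is.null(names(subject)))
    subject <- as.data.frame(as.list(subject))
  model <- score$model
  attr_set <- shap_values(model, subject)
  risk <- as.numeric(predict_risk(model, subject))
  base_risk <- mean(predict_risk(model, model$train_x))
  phi <- attr_set$phi[1, ]
  s <- sum(phi)
  contrib <- if (abs(s) < 1e-12) phi * 0 else phi * (risk - base_risk) / s
  vals <- as.numeric(as.data.frame(subject)[1, model$features])
  ord <- order(-abs(contrib), names(contrib))
  structure(
    list(risk = risk, base = base_risk,
         contributions = data.frame(feature = names(contrib)[ord],
                                    value = vals[ord],
                                    contribution = unname(contrib[ord]),
                                    row.names = NULL)),
    class = "individual_explanation")
}

#' @export
print.individual_explanation <- function(x, n = 10, ...) {
  cat(sprintf("Risk score %.3f (base value %.3f)\n", x$risk, x$base))
  top <- utils::head(x$contributions, n)
  for (i in seq_len(nrow(top))) {
    arrow <- if (top$contribution[i] >= 0) "+" else "-"
    cat(sprintf("  %s %-22s %8.3g  ->  %+0.4f\n", arrow, top$feature[i],
                top$value[i], top$contribution[i]))
  }
  invisible(x)
}
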