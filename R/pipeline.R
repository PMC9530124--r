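# End-to-end pipeline: simulate -> split -> train -> attribute ->
# redundancy -> reference-interval audit -> risk score, with per-stage
# seeds fanned out from one root seed and a hash manifest for
# reproducibility checks.

#' Build a validated pipeline configuration
#'
#' @param out_dir artifact directory (created if absent).
#' @param spec a [cohort_spec()] to simulate, or `NULL` when `data_path`
#'   points at an existing cohort csv.
#' @param data_path optional path to a cohort written by [write_cohort()].
#' @param horizon label horizon to model (e.g. `"5y"`).
#' @param split_mode `"random"` or `"temporal"`.
#' @param split_cutoff cycle cutoff for temporal splits.
#' @param grid single-row hyperparameter grid for model fits.
#' @param n_boot bootstrap replicates for evaluations.
#' @param max_distance_features supervised distances are computed over at
#'   most this many features (the most important ones).
#' @param tier risk-score tier name.
#' @param risk_size risk-score feature count.
#' @param stages character vector of stages to run (in pipeline order).
#' @param seed root seed fanned out to every stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, spec = NULL, data_path = NULL, horizon = "5y",
                       split_mode = c("random", "temporal"), split_cutoff = NULL,
                       grid = NULL, n_boot = 200, max_distance_features = 10,
                       tier = "all", risk_size = 8,
                       stages = c("simulate", "split", "train", "attribution",
                                  "redundancy", "rrp", "riskscore"),
                       seed = 1L) {
  split_mode <- match.arg(split_mode)
  if (is.null(spec) && is.null(data_path))
    stop_tm("config needs either a simulation spec or a data path")
  if (!is.null(spec) && !inherits(spec, "cohort_spec"))
    stop_tm("spec must be a cohort_spec")
  if (!is.null(data_path) && !file.exists(data_path))
    stop_tm("data_path does not exist: ", data_path)
  if (!grepl("^[0-9]+y$", horizon)) stop_tm("horizon must look like '5y'")
  if (split_mode == "temporal" && is.null(split_cutoff))
    stop_tm("temporal split requires a cutoff")
  grid <- grid %||% data.frame(max_depth = 3, eta = 0.1, nrounds = 150,
                               min_child_weight = 1)
  structure(list(out_dir = out_dir, spec = spec, data_path = data_path,
                 horizon = horizon, split_mode = split_mode,
                 split_cutoff = split_cutoff, grid = grid, n_boot = n_boot,
                 max_distance_features = max_distance_features, tier = tier,
                 risk_size = risk_size, stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; a `spec` block
#' with `n_subjects`/`n_noise_features`/`missingness`/`seed` builds a
#' [default_cohort_spec()] variant.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$spec))
    do.call(default_cohort_spec, y$spec)
  run_config(out_dir = y$out_dir, spec = spec, data_path = y$data_path,
             horizon = y$horizon %||% "5y",
             split_mode = y$split_mode %||% "random",
             split_cutoff = y$split_cutoff,
             n_boot = y$n_boot %||% 200,
             max_distance_features = y$max_distance_features %||% 10,
             tier = y$tier %||% "all", risk_size = y$risk_size %||% 8,
             seed = y$seed %||% 1L)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_tm(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, persisting every artifact as
#' delimited text or JSON under `out_dir`, and finishes with a manifest
#' listing per-stage seeds and md5 hashes of all artifacts. A rerun with the
#' same configuration and seed reproduces identical hashes for the
#' deterministic stages. A stage failure halts the run with the stage name;
#' artifacts of earlier stages remain on disk.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the artifact directory, the manifest, and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- fan_seeds(config$seed, c("simulate", "split", "train", "attribution",
                                    "redundancy", "rrp", "riskscore"))
  res <- list()
  art <- function(name) file.path(config$out_dir, name)
  stages <- config$stages

  # --- cohort -------------------------------------------------------------
  if (!is.null(config$spec) && "simulate" %in% stages) {
    cohort <- run_stage("simulate", generate_cohort(config$spec, seed = seeds[["simulate"]]))
    run_stage("simulate",
              write_cohort(cohort$table, art("cohort.csv"), labels = cohort$labels,
                           truth = cohort$truth))
    ft <- cohort$table
    labels_all <- cohort$labels
    res$cohort <- cohort
  } else {
    loaded <- run_stage("load", read_cohort(config$data_path))
    ft <- loaded$table; labels_all <- loaded$labels
  }
  if (!config$horizon %in% colnames(labels_all))
    stop_tm("pipeline stage 'split' failed: no labels for horizon ", config$horizon)
  labels <- labels_all[, config$horizon]

  # --- split --------------------------------------------------------------
  split <- run_stage("split", split_cohort(
    ft, mode = config$split_mode, cutoff = config$split_cutoff,
    seed = seeds[["split"]]))
  jsonlite::write_json(list(mode = config$split_mode, train = split$train),
                       art("split.json"), auto_unbox = TRUE)

  # --- train --------------------------------------------------------------
  if ("train" %in% stages) {
    res$model <- run_stage("train", fit_gbt(
      ft_subset(ft, rows = split$train), labels[split$train],
      grid = config$grid, seed = seeds[["train"]]))
    res$baseline <- run_stage("train", fit_linear_baseline(
      ft_subset(ft, rows = split$train), labels[split$train],
      seed = seeds[["train"]]))
    test_ft <- ft_subset(ft, rows = split$test)
    ev_gbt <- evaluate_auroc(predict_risk(res$model, test_ft), labels[split$test],
                             n_boot = config$n_boot, seed = seeds[["train"]])
    ev_lin <- evaluate_auroc(predict_risk(res$baseline, test_ft), labels[split$test],
                             n_boot = config$n_boot, seed = seeds[["train"]])
    res$evaluation <- data.frame(
      model = c("gbt", "logistic"),
      auroc = c(ev_gbt$auroc, ev_lin$auroc),
      ci_lo = c(ev_gbt$ci[1], ev_lin$ci[1]),
      ci_hi = c(ev_gbt$ci[2], ev_lin$ci[2]))
    utils::write.csv(res$evaluation, art("model_eval.csv"), row.names = FALSE)
  }

  # --- attribution --------------------------------------------------------
  if ("attribution" %in% stages) {
    fg <- with_seed(seeds[["attribution"]],
                    sample(split$train, min(length(split$train), 1000L)))
    attr_set <- run_stage("attribution",
                          shap_values(res$model, ft_subset(ft, rows = fg)))
    res$importance <- shap_importance(attr_set)
    utils::write.csv(res$importance, art("importance.csv"), row.names = FALSE)
  }

  # --- redundancy ---------------------------------------------------------
  if ("redundancy" %in% stages) {
    top <- utils::head(res$importance$feature, config$max_distance_features)
    res$distance <- run_stage("redundancy", supervised_distance_matrix(
      ft, labels, train = split$train, features = sort(top)))
    utils::write.csv(as.data.frame(res$distance$distance),
                     art("distance_matrix.csv"))
  }

  # --- reference-interval audit -------------------------------------------
  if ("rrp" %in% stages && !is.null(res$cohort)) {
    ris <- res$cohort$truth$reference_intervals
    intervals <- unlist(lapply(ris, function(x) list(x$optimal, x$misset)),
                        recursive = FALSE)
    models <- stats::setNames(list(res$model), config$horizon)
    res$audit <- run_stage("rrp", audit_intervals(
      models, ft_subset(ft, rows = split$test), intervals))
    res$audit$kind <- rep(c("optimal", "misset"), length(ris))
    utils::write.csv(res$audit, art("rrp_audit.csv"), row.names = FALSE)
  }

  # --- risk score ---------------------------------------------------------
  if ("riskscore" %in% stages) {
    res$risk_score <- run_stage("riskscore", build_risk_score(
      ft, labels, split, tier = feature_tier(ft, config$tier),
      size = config$risk_size, grid = config$grid, n_boot = config$n_boot,
      seed = seeds[["riskscore"]]))
    rs <- res$risk_score
    jsonlite::write_json(
      list(tier = rs$tier, size = rs$size, features = rs$features,
           auroc = rs$evaluations$overall$auroc,
           ci = rs$evaluations$overall$ci),
      art("risk_score.json"), auto_unbox = TRUE, digits = NA)
    subj <- ft_subset(ft, rows = split$test[1])
    expl <- explain_individual(rs, subj$data)
    jsonlite::write_json(
      list(risk = expl$risk, base = expl$base, contributions = expl$contributions),
      art("explanation.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(hashes) <- files
  manifest <- list(package_version = as.character(utils::packageVersion("treemort")),
                   seed = config$seed, stage_seeds = as.list(seeds),
                   horizon = config$horizon, hashes = hashes)
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE)
  invisible(c(list(dir = config$out_dir, manifest = manifest), res))
}
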