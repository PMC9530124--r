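# Synthetic cohort generation: planted effects, redundancy, nested labels.

# Contribution of one planted effect, vectorized over subjects.
effect_contribution <- function(spec, e, v, partner_v = NULL) {
  m <- spec_marginal(spec, e$feature)
  z <- (v - marg_mean(m)) / marg_sd(m)
  switch(e$shape,
    monotone = e$weight * z,
    u_shape = e$weight * e$curvature * ((v - e$v0) / marg_sd(m))^2,
    threshold = {
      lo <- marg_range(m)[1]
      ramp <- pmin(pmax((v - lo) / (e$v_t - lo), 0), 1)
      e$weight * e$plateau * ramp
    },
    interaction = {
      mp <- spec_marginal(spec, e$partner)
      zp <- (partner_v - marg_mean(mp)) / marg_sd(mp)
      e$weight * z * zp
    })
}

# Sum of planted contributions (no intercept), given complete feature data.
linear_predictor <- function(spec, data) {
  eta <- numeric(nrow(data))
  for (e in spec$effects) {
    if (!e$feature %in% names(data))
      stop_tm(sprintf("feature '%s' required by a planted effect is missing", e$feature))
    pv <- if (e$shape == "interaction") {
      if (!e$partner %in% names(data))
        stop_tm(sprintf("interaction partner '%s' is missing", e$partner))
      data[[e$partner]]
    }
    eta <- eta + effect_contribution(spec, e, data[[e$feature]], pv)
  }
  eta
}

# Sum of contributions involving `feature` (as target or interaction partner)
# when that feature is set to `values`, other columns taken from `data`.
feature_contribution <- function(spec, feature, values, data) {
  out <- numeric(length(values))
  for (e in spec$effects) {
    if (e$feature == feature) {
      pv <- if (e$shape == "interaction") data[[e$partner]]
      out <- out + effect_contribution(spec, e, values, pv)
    } else if (e$shape == "interaction" && identical(e$partner, feature)) {
      out <- out + effect_contribution(spec, e, data[[e$feature]], values)
    }
  }
  out
}

# fixed catalogue of monotone transforms used for redundancy-group members
member_transforms <- list(
  function(x) x,
  function(x) x + 0.2 * x^3,
  function(x) exp(x / 2),
  function(x) atan(x),
  function(x) sign(x) * sqrt(abs(x))
)

#' Generate a synthetic cohort with planted structure
#'
#' Draws features from the spec's marginals, builds redundancy-group members
#' as noisy monotone transforms of shared latents, computes the logistic
#' mortality mechanism, draws nested binary labels per follow-up horizon, and
#' applies MCAR missingness to non-demographic features. Identical spec and
#' seed give byte-identical output.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{table}{the [feature_table()] (with missingness applied),}
#'     \item{labels}{integer matrix of subjects x horizons,}
#'     \item{truth}{a `ground_truth` object holding true per-subject event
#'       probabilities, the complete (pre-missingness) features, redundancy
#'       assignments, and planted reference intervals,}
#'     \item{spec}{the spec.}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(n_subjects = 300, seed = 2))
#' cohort$table
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (e in spec$effects) if (!is.finite(e$weight)) stop_tm("non-finite effect weight")
  if (spec$missingness >= 1) stop_tm("missingness must be < 1")
  seed <- seed %||% spec$seed
  n <- spec$n_subjects
  feats <- spec$features
  members <- unlist(lapply(spec$redundancy_groups, `[[`, "members"))

  with_seed(seed, {
    df <- as.data.frame(matrix(NA_real_, n, length(feats),
                               dimnames = list(NULL, feats)))
    # independent features, in fixed catalogue order
    for (f in setdiff(feats, members)) df[[f]] <- marg_sample(spec_marginal(spec, f), n)
    # redundancy groups: members share one latent
    group_assign <- character(0)
    for (g in spec$redundancy_groups) {
      latent <- stats::rnorm(n)
      for (k in seq_along(g$members)) {
        f <- g$members[k]
        gk <- member_transforms[[(k - 1L) %% length(member_transforms) + 1L]](latent)
        zk <- (gk - mean(gk)) / stats::sd(gk)
        m <- spec_marginal(spec, f)
        df[[f]] <- marg_mean(m) + marg_sd(m) * (zk + stats::rnorm(n, 0, g$noise_sd))
        group_assign[f] <- g$latent
      }
    }

    eta0 <- linear_predictor(spec, df)
    H <- length(spec$horizons)
    prob <- matrix(NA_real_, n, H, dimnames = list(NULL, names(spec$horizon_shifts)))
    for (h in seq_len(H)) prob[, h] <- sigmoid(spec$beta0 + spec$horizon_shifts[h] + eta0)
    u <- stats::runif(n)                       # shared latent draw => nested labels
    labels <- matrix(0L, n, H, dimnames = dimnames(prob))
    labels[] <- as.integer(u < prob)

    cycle <- sample.int(spec$n_cycles, n, replace = TRUE)

    df_obs <- df
    if (spec$missingness > 0) {
      for (f in feats[spec$roles[feats] != "demographic"]) {
        drop <- stats::runif(n) < spec$missingness
        df_obs[[f]][drop] <- NA_real_
      }
    }

    truth <- structure(
      list(prob = prob, eta = eta0, features_complete = df,
           group_assign = group_assign, effects = spec$effects, spec = spec),
      class = "ground_truth")
    truth$reference_intervals <- plant_reference_intervals(truth)

    structure(
      list(table = feature_table(df_obs, spec$roles, cycle = cycle),
           labels = labels, truth = truth, spec = spec),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort\n")
  print(x$table)
  cat("  event rates:",
      paste(sprintf("%s=%.3f", colnames(x$labels), colMeans(x$labels)), collapse = "  "),
      "\n")
  invisible(x)
}

#' True planted event probability
#'
#' Evaluates the exact logistic mortality mechanism of a spec on supplied
#' feature values; the oracle against which model-based recovery is judged.
#'
#' @param spec a [cohort_spec()].
#' @param newdata data.frame containing every feature named by a planted
#'   effect (and interaction partners).
#' @param horizon follow-up horizon in years (must be one of the spec's).
#' @return Vector of event probabilities.
#' @export
true_risk <- function(spec, newdata, horizon = 5) {
  stopifnot(inherits(spec, "cohort_spec"))
  key <- paste0(horizon, "y")
  if (!key %in% names(spec$horizon_shifts)) stop_tm("unknown horizon: ", horizon)
  sigmoid(spec$beta0 + spec$horizon_shifts[[key]] + linear_predictor(spec, as.data.frame(newdata)))
}

#' True relative-risk curve of a planted feature
#'
#' For each grid value v, every subject's feature is counterfactually set to
#' v in the true mechanism; the mean true probability is divided by the
#' cohort's unmodified mean true probability.
#'
#' @param truth a `ground_truth` object from [generate_cohort()].
#' @param feature feature name.
#' @param horizon follow-up horizon in years.
#' @param grid numeric grid (default: 201 points over the 0.5--99.5
#'   percentiles of the realized feature values).
#' @return data.frame with columns `value` and `rr`.
#' @export
true_relative_risk <- function(truth, feature, horizon = 5, grid = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  spec <- truth$spec
  key <- paste0(horizon, "y")
  if (!key %in% names(spec$horizon_shifts)) stop_tm("unknown horizon: ", horizon)
  data <- truth$features_complete
  if (!feature %in% names(data)) stop_tm("unknown feature: ", feature)
  if (is.null(grid)) {
    q <- stats::quantile(data[[feature]], c(0.005, 0.995), names = FALSE)
    grid <- seq(q[1], q[2], length.out = 201)
  }
  shift <- spec$beta0 + spec$horizon_shifts[[key]]
  base_contrib <- feature_contribution(spec, feature, data[[feature]], data)
  denom <- mean(sigmoid(shift + truth$eta))
  rr <- vapply(grid, function(v) {
    cv <- feature_contribution(spec, feature, rep(v, nrow(data)), data)
    mean(sigmoid(shift + truth$eta - base_contrib + cv)) / denom
  }, numeric(1))
  data.frame(value = grid, rr = rr)
}

#' Derive planted reference intervals for a feature
#'
#' From the true relative-risk curve, builds one "optimal" interval covering
#' the low-risk region around the risk minimum (true relative risk at or
#' below 1) and one deliberately "mis-set" interval containing the feature
#' value of maximal true relative risk. Features without a planted effect, or
#' whose true curve is flat, are rejected.
#'
#' @param truth a `ground_truth` object.
#' @param feature feature name.
#' @param horizon follow-up horizon in years.
#' @return List with elements `optimal` and `misset`, each a
#'   [reference_interval()].
#' @export
make_reference_intervals <- function(truth, feature, horizon = 5) {
  stopifnot(inherits(truth, "ground_truth"))
  spec <- truth$spec
  involved <- vapply(spec$effects, function(e)
    e$feature == feature || identical(e$partner, feature), logical(1))
  if (!any(involved)) stop_tm(sprintf("feature '%s' has no planted effect", feature))
  curve <- true_relative_risk(truth, feature, horizon = horizon)
  r <- curve$rr; v <- curve$value
  if (diff(range(r)) < 0.02)
    stop_tm(sprintf("feature '%s' has a flat true risk curve; no meaningful interval", feature))

  i_min <- which.min(r); i_max <- which.max(r)
  n_grid <- length(r)
  run_around <- function(center, ok) {
    lo <- center; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- center; while (hi < n_grid && ok[hi + 1L]) hi <- hi + 1L
    c(lo, hi)
  }
  # optimal: the clearly-low-risk sub-run around the minimum, with a buffer
  # below the cohort-average line so that estimation noise near the r = 1
  # crossing does not spill risk into the interval
  low_ok <- r <= 1 - 0.33 * (1 - min(r))
  run <- run_around(i_min, low_ok)
  if (diff(run) < 4L) run <- run_around(i_min, r <= 1)
  if (diff(run) < 2L) run <- c(max(1L, i_min - 2L), min(n_grid, i_min + 2L))
  optimal <- reference_interval(feature, v[run[1]], v[run[2]])

  # mis-set: the high-risk run around the maximum (relative risk at least
  # halfway from the average line to the maximum), expanded slightly
  high_ok <- r >= 1 + 0.5 * (max(r) - 1)
  mrun <- run_around(i_max, high_ok)
  mrun <- c(max(1L, mrun[1] - 5L), min(n_grid, mrun[2] + 5L))
  misset <- reference_interval(feature, v[mrun[1]], v[mrun[2]])
  list(optimal = optimal, misset = misset)
}

# RIs for features carrying a substantial main effect (|weight| >= 0.5 among
# non-interaction terms). Interaction-dominated features are excluded: their
# risk profile depends on the partner, so a single-population reference
# interval is not meaningful. Demographics excluded; flat features skipped.
plant_reference_intervals <- function(truth) {
  spec <- truth$spec
  eligible <- unique(unlist(lapply(spec$effects, function(e)
    if (e$shape != "interaction" && abs(e$weight) >= 0.5) e$feature)))
  eligible <- setdiff(eligible, names(spec$roles)[spec$roles == "demographic"])
  out <- list()
  for (f in eligible) {
    ri <- tryCatch(make_reference_intervals(truth, f), error = function(e) NULL)
    if (!is.null(ri)) out[[f]] <- ri
  }
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth for a synthetic cohort\n")
  cat(sprintf("  subjects: %d   planted effects: %d   redundancy members: %d\n",
              nrow(x$prob), length(x$effects), length(x$group_assign)))
  cat(sprintf("  planted reference intervals: %s\n",
              paste(names(x$reference_intervals), collapse = ", ")))
  invisible(x)
}
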