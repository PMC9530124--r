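#' Describe a planted risk effect
#'
#' A planted effect is one additive term of the synthetic cohort's mortality
#' mechanism, expressed on the log-odds scale. Four shapes are supported:
#'
#' * `"monotone"` — `weight * z`, where `z` is the feature standardized by its
#'   marginal mean and sd.
#' * `"u_shape"` — `weight * curvature * ((v - v0) / sd)^2`: zero at the
#'   optimum `v0` and rising quadratically away from it, the classic U-shaped
#'   risk profile of analytes such as serum urate.
#' * `"threshold"` — a linear ramp from the low end of the sampling range up
#'   to the knot `v_t`, saturating at `weight * plateau` above it, so values
#'   beyond the knot all carry the same risk.
#' * `"interaction"` — `weight * z * z_partner`, a multiplicative log-odds
#'   interaction with a second feature (e.g. an exposure whose effect is
#'   stronger in the young).
#'
#' @param feature name of the feature the effect acts on.
#' @param shape one of `"monotone"`, `"u_shape"`, `"threshold"`,
#'   `"interaction"`.
#' @param weight log-odds coefficient; must be finite.
#' @param v0 optimum of a U-shaped effect (feature units).
#' @param curvature positive curvature multiplier of a U-shaped effect.
#' @param v_t knot of a threshold effect (feature units).
#' @param plateau saturation level multiplier of a threshold effect.
#' @param partner partner feature name for an interaction effect.
#' @return An object of class `planted_effect`.
#' @export
#' @examples
#' planted_effect("urate", "u_shape", weight = 0.8, v0 = 5, curvature = 0.5)
planted_effect <- function(feature,
                           shape = c("monotone", "u_shape", "threshold", "interaction"),
                           weight,
                           v0 = NULL, curvature = 1,
                           v_t = NULL, plateau = 1,
                           partner = NULL) {
  shape <- match.arg(shape)
  if (!is.character(feature) || length(feature) != 1L || !nzchar(feature))
    stop_tm("'feature' must be a single non-empty name")
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight))
    stop_tm(sprintf("effect on '%s': weight must be finite", feature))
  if (shape == "u_shape") {
    assert_scalar_number(v0, "v0")
    assert_scalar_number(curvature, "curvature")
    if (curvature <= 0) stop_tm("u_shape curvature must be positive")
  }
  if (shape == "threshold") {
    assert_scalar_number(v_t, "v_t")
    assert_scalar_number(plateau, "plateau")
  }
  if (shape == "interaction") {
    if (!is.character(partner) || length(partner) != 1L)
      stop_tm("interaction effect requires a partner feature name")
    if (identical(partner, feature))
      stop_tm("interaction partner must differ from the feature itself")
  }
  structure(
    list(feature = feature, shape = shape, weight = weight,
         v0 = v0, curvature = curvature, v_t = v_t, plateau = plateau,
         partner = partner),
    class = "planted_effect"
  )
}

#' Describe a group of mutually redundant features
#'
#' Members of a redundancy group are noisy monotone transforms of one shared
#' latent variable, emulating clusters such as the anthropometric block
#' (arm circumference, BMI, waist, weight) in population survey data.
#'
#' @param latent name of the latent variable (bookkeeping only).
#' @param members character vector of at least two member feature names.
#' @param noise_sd per-member noise standard deviation on the standardized
#'   member scale (the latent has sd 1 after standardization).
#' @return An object of class `redundancy_group`.
#' @export
redundancy_group <- function(latent, members, noise_sd = 0.05) {
  if (length(members) < 2L) stop_tm("a redundancy group needs >= 2 members")
  if (anyDuplicated(members)) stop_tm("duplicate member names in redundancy group")
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_tm("noise_sd must be >= 0")
  structure(list(latent = latent, members = as.character(members),
                 noise_sd = noise_sd),
            class = "redundancy_group")
}

marg_normal <- function(mean = 5, sd = 1) list(dist = "normal", mean = mean, sd = sd)
marg_lognormal <- function(meanlog = 1.5, sdlog = 0.4) list(dist = "lognormal", meanlog = meanlog, sdlog = sdlog)
marg_uniform <- function(min, max) list(dist = "uniform", min = min, max = max)
marg_bernoulli <- function(p = 0.5) list(dist = "bernoulli", p = p)

marg_mean <- function(m) {
  switch(m$dist,
    normal = m$mean,
    lognormal = exp(m$meanlog + m$sdlog^2 / 2),
    uniform = (m$min + m$max) / 2,
    bernoulli = m$p)
}

marg_sd <- function(m) {
  switch(m$dist,
    normal = m$sd,
    lognormal = sqrt((exp(m$sdlog^2) - 1)) * exp(m$meanlog + m$sdlog^2 / 2),
    uniform = (m$max - m$min) / sqrt(12),
    bernoulli = sqrt(m$p * (1 - m$p)))
}

marg_range <- function(m) {
  switch(m$dist,
    normal = c(m$mean - 4 * m$sd, m$mean + 4 * m$sd),
    lognormal = stats::qlnorm(c(0.001, 0.999), m$meanlog, m$sdlog),
    uniform = c(m$min, m$max),
    bernoulli = c(0, 1))
}

marg_sample <- function(m, n) {
  switch(m$dist,
    normal = stats::rnorm(n, m$mean, m$sd),
    lognormal = stats::rlnorm(n, m$meanlog, m$sdlog),
    uniform = stats::runif(n, m$min, m$max),
    bernoulli = stats::rbinom(n, 1, m$p))
}

#' Specify a synthetic survey-like cohort
#'
#' Defines the generative mechanism for [generate_cohort()]: feature
#' marginals, planted risk effects, redundancy groups, pure-noise features,
#' missingness, and a logistic mortality mechanism with one baseline log-odds
#' per follow-up horizon. `age` (uniform on 18--85, demographic) and `sex`
#' (Bernoulli(0.5), demographic) are always present; continuous features
#' default to Normal(5, 1) marginals unless overridden via `marginals`.
#'
#' The per-horizon linear predictor is
#' `eta_h = beta0 + shift_h + sum(planted effect contributions)`, the event
#' probability is `plogis(eta_h)`, and labels across horizons are nested: one
#' latent uniform draw per subject is compared against the increasing
#' sequence of probabilities, so death by a short horizon implies death by
#' every longer one.
#'
#' @param n_subjects positive number of subjects.
#' @param effects list of [planted_effect()] terms.
#' @param redundancy_groups list of [redundancy_group()]s.
#' @param n_noise_features number of pure-noise questionnaire features.
#' @param missingness MCAR missingness fraction in `[0, 1)`, applied to all
#'   non-demographic features.
#' @param beta0 baseline log-odds at the reference horizon (the horizon with
#'   shift 0).
#' @param horizons integer follow-up horizons in years.
#' @param horizon_shifts log-odds shift per horizon (same length as
#'   `horizons`, non-decreasing); defaults to a spread that makes event rates
#'   grow with follow-up time.
#' @param marginals named list of marginal overrides (see `marg_normal()` and
#'   friends in the package source).
#' @param roles named character vector of role overrides
#'   (`demographic`/`examination`/`laboratory`/`questionnaire`).
#' @param n_cycles number of enrollment cycles for temporal splits.
#' @param seed integer seed stored with the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        effects = list(),
                        redundancy_groups = list(),
                        n_noise_features = 0L,
                        missingness = 0.05,
                        beta0 = stats::qlogis(0.1),
                        horizons = c(1, 3, 5, 10),
                        horizon_shifts = NULL,
                        marginals = list(),
                        roles = character(),
                        n_cycles = 8L,
                        seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) stop_tm("n_subjects must be >= 1")
  if (!is.numeric(missingness) || missingness < 0 || missingness >= 1)
    stop_tm("missingness must lie in [0, 1)")
  assert_scalar_number(beta0, "beta0")
  if (is.null(horizon_shifts)) {
    # spread baseline rates across horizons around the reference beta0
    horizon_shifts <- stats::setNames(
      c(-1.2, -0.5, 0, 0.8)[seq_along(horizons)], paste0(horizons, "y"))
    horizon_shifts[is.na(horizon_shifts)] <- 0
  } else {
    if (length(horizon_shifts) != length(horizons))
      stop_tm("horizon_shifts must match horizons in length")
    horizon_shifts <- stats::setNames(horizon_shifts, paste0(horizons, "y"))
  }
  if (is.unsorted(horizon_shifts)) stop_tm("horizon_shifts must be non-decreasing")
  for (e in effects) if (!inherits(e, "planted_effect"))
    stop_tm("all 'effects' must be planted_effect objects")
  for (g in redundancy_groups) if (!inherits(g, "redundancy_group"))
    stop_tm("all 'redundancy_groups' must be redundancy_group objects")

  members <- unlist(lapply(redundancy_groups, `[[`, "members"))
  if (anyDuplicated(members))
    stop_tm("a feature appears in more than one redundancy group")

  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         effects = effects,
         redundancy_groups = redundancy_groups,
         n_noise_features = as.integer(n_noise_features),
         missingness = missingness,
         beta0 = beta0,
         horizons = horizons,
         horizon_shifts = horizon_shifts,
         marginals = marginals,
         roles_override = roles,
         n_cycles = as.integer(n_cycles),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  spec$features <- spec_feature_names(spec)
  spec$roles <- spec_roles(spec)
  if (anyDuplicated(spec$features)) stop_tm("feature names must be unique")

  # parameter sanity against sampling ranges
  for (e in effects) {
    rng <- marg_range(spec_marginal(spec, e$feature))
    if (e$shape == "u_shape" && (e$v0 <= rng[1] || e$v0 >= rng[2]))
      stop_tm(sprintf("u_shape optimum for '%s' lies outside its sampling range", e$feature))
    if (e$shape == "threshold" && (e$v_t <= rng[1] || e$v_t >= rng[2]))
      stop_tm(sprintf("threshold knot for '%s' lies outside its sampling range", e$feature))
  }
  spec
}

spec_feature_names <- function(spec) {
  members <- unlist(lapply(spec$redundancy_groups, `[[`, "members"))
  eff <- unlist(lapply(spec$effects, function(e) c(e$feature, e$partner)))
  noise <- if (spec$n_noise_features > 0)
    sprintf("noise_%02d", seq_len(spec$n_noise_features)) else character()
  unique(c("age", "sex", members, eff, noise))
}

spec_roles <- function(spec) {
  feats <- spec_feature_names(spec)
  members <- unlist(lapply(spec$redundancy_groups, `[[`, "members"))
  roles <- stats::setNames(rep("laboratory", length(feats)), feats)
  roles[feats %in% members] <- "examination"
  roles[grepl("^noise_", feats)] <- "questionnaire"
  roles[c("age", "sex")] <- "demographic"
  ov <- spec$roles_override
  if (length(ov)) roles[names(ov)] <- ov
  roles
}

spec_marginal <- function(spec, feature) {
  if (!is.null(spec$marginals[[feature]])) return(spec$marginals[[feature]])
  if (feature == "age") return(marg_uniform(18, 85))
  if (feature == "sex") return(marg_bernoulli(0.5))
  marg_normal(5, 1)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  subjects: %d   features: %d   noise: %d   missingness: %.2f\n",
              x$n_subjects, length(x$features), x$n_noise_features, x$missingness))
  cat(sprintf("  horizons: %s   baseline rate (ref): %.3f\n",
              paste0(x$horizons, "y", collapse = ", "), stats::plogis(x$beta0)))
  cat(sprintf("  planted effects: %d   redundancy groups: %d\n",
              length(x$effects), length(x$redundancy_groups)))
  invisible(x)
}

#' A ready-made cohort specification with every planted structure
#'
#' The default study conditions used throughout the package's examples and
#' checks: an age effect, a U-shaped urate effect, a saturating urine-albumin
#' threshold, a monotone red-cell-distribution-width effect, a blood-lead
#' effect with an age interaction and a sex interaction, a four-member
#' anthropometric redundancy group whose `arm_circumference` member carries a
#' protective monotone effect, and pure-noise questionnaire features.
#'
#' @param n_subjects cohort size (default 5000).
#' @param n_noise_features number of noise features (default 8).
#' @param missingness MCAR fraction (default 0.05).
#' @param seed integer seed.
#' @return A [cohort_spec()].
#' @export
#' @examples
#' spec <- default_cohort_spec(n_subjects = 500, seed = 7)
#' cohort <- generate_cohort(spec)
#' colMeans(cohort$labels)
default_cohort_spec <- function(n_subjects = 5000, n_noise_features = 8,
                                missingness = 0.05, seed = 1L) {
  cohort_spec(
    n_subjects = n_subjects,
    effects = list(
      planted_effect("age", "monotone", weight = 1.2),
      planted_effect("urate", "u_shape", weight = 0.9, v0 = 4.6, curvature = 0.5),
      planted_effect("urine_albumin", "threshold", weight = 1.0, v_t = 5.8),
      planted_effect("rdw", "monotone", weight = 0.7),
      planted_effect("lead", "monotone", weight = 0.4),
      planted_effect("lead", "interaction", weight = -0.5, partner = "age"),
      planted_effect("arm_circumference", "monotone", weight = -0.6)
    ),
    redundancy_groups = list(
      redundancy_group("body_size",
                       c("arm_circumference", "bmi", "waist", "weight"),
                       noise_sd = 0.05)
    ),
    n_noise_features = n_noise_features,
    missingness = missingness,
    beta0 = stats::qlogis(0.03),
    seed = seed
  )
}
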