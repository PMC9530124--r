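# Relative-risk partial dependence and reference-interval auditing.

#' Construct a laboratory reference interval
#'
#' @param feature feature name.
#' @param low,high interval bounds in feature units, `low < high`.
#' @param sex optional sex stratum (`0`/`1` or a label matching the cohort's
#'   `sex` coding) for sex-specific intervals.
#' @return An object of class `reference_interval`.
#' @export
reference_interval <- function(feature, low, high, sex = NA) {
  assert_scalar_number(low, "low"); assert_scalar_number(high, "high")
  if (low >= high) stop_tm("reference interval requires low < high")
  structure(list(feature = feature, low = low, high = high, sex = sex),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("Reference interval for %s: [%.3g, %.3g]%s\n", x$feature, x$low,
              x$high, if (is.na(x$sex)) "" else paste0(" (sex = ", x$sex, ")")))
  invisible(x)
}

#' Relative-risk partial-dependence curve
#'
#' For each grid value v, the feature is set to v for every subject, the mean
#' predicted event probability is computed, and the result is divided by the
#' unmodified mean prediction, so `r(v) = 1` is the cohort-average risk line.
#'
#' @param model a fitted `mortality_model`.
#' @param newdata a [feature_table()] or data.frame of evaluation subjects
#'   (typically the test split).
#' @param feature feature to vary (must be a model feature).
#' @param grid numeric grid; default 100 points at the empirical 0.5--99.5
#'   percentiles of the observed values.
#' @param n_grid grid size when `grid` is `NULL`.
#' @return An object of class `relative_risk_curve`: list with `curve`
#'   (data.frame of `value`, `rr`), `feature`, `mean_pred`, and `observed`
#'   (the observed feature values, for histograms).
#' @export
relative_risk_curve <- function(model, newdata, feature, grid = NULL, n_grid = 100) {
  data <- if (inherits(newdata, "feature_table")) newdata$data else as.data.frame(newdata)
  if (!feature %in% model$features)
    stop_tm(sprintf("feature '%s' is not part of the model", feature))
  obs <- data[[feature]]
  if (is.null(grid)) {
    q <- stats::quantile(obs, c(0.005, 0.995), na.rm = TRUE, names = FALSE)
    grid <- seq(q[1], q[2], length.out = n_grid)
  }
  if (length(grid) == 0) stop_tm("empty grid")
  mean_pred <- mean(predict_risk(model, data))
  rr <- vapply(grid, function(v) {
    d <- data; d[[feature]] <- v
    mean(predict_risk(model, d)) / mean_pred
  }, numeric(1))
  structure(list(curve = data.frame(value = grid, rr = rr), feature = feature,
                 mean_pred = mean_pred, observed = obs),
            class = "relative_risk_curve")
}

#' @export
print.relative_risk_curve <- function(x, ...) {
  cat(sprintf("Relative-risk curve for %s: %d grid points, r in [%.3f, %.3f]\n",
              x$feature, nrow(x$curve), min(x$curve$rr), max(x$curve$rr)))
  invisible(x)
}

#' @export
plot.relative_risk_curve <- function(x, ri = NULL, ...) {
  graphics::plot(x$curve$value, x$curve$rr, type = "l", xlab = x$feature,
                 ylab = "relative risk", ...)
  graphics::abline(h = 1, lty = 3, col = "grey40")
  if (!is.null(ri)) graphics::rect(ri$low, graphics::par("usr")[3], ri$high,
                                   graphics::par("usr")[4],
                                   col = grDevices::adjustcolor("green", 0.15),
                                   border = NA)
  invisible(x)
}

#' Relative risk percentage of a reference interval
#'
#' Scores how much of a feature's maximal elevated risk lies inside its
#' reference interval:
#' `RRP = 100 * (max r(v) inside the RI - 1) / (max r(v) overall - 1)`.
#' It is 100% when the interval contains the global risk maximum, negative
#' when risk inside the interval stays below the cohort average, and 0 by
#' convention for a flat curve. A higher RRP flags a possibly sub-optimal
#' interval.
#'
#' @param curve a [relative_risk_curve()].
#' @param ri a [reference_interval()].
#' @param threshold RRP percentage above which the interval is flagged
#'   sub-optimal (default 50).
#' @param flat_eps curves whose maximum excess risk is below this are
#'   treated as flat.
#' @return An object of class `rrp_result`: list with `rrp` (signed
#'   percentage, at most 100), `flagged`, `feature`, `ri`.
#' @export
rrp <- function(curve, ri, threshold = 50, flat_eps = 1e-3) {
  stopifnot(inherits(curve, "relative_risk_curve"), inherits(ri, "reference_interval"))
  v <- curve$curve$value; r <- curve$curve$rr
  inside <- v >= ri$low & v <= ri$high
  if (!any(inside)) stop_tm("no grid point falls inside the reference interval")
  max_all <- max(r) - 1
  max_in <- max(r[inside]) - 1
  # snap numerical ties to the saturating value
  if (max_in >= max_all - 1e-9 * (1 + abs(max_all))) max_in <- max_all
  value <- if (max_all < flat_eps) 0 else 100 * (max_in / max_all)
  structure(list(rrp = value, flagged = value > threshold, threshold = threshold,
                 feature = curve$feature, ri = ri),
            class = "rrp_result")
}

#' @export
print.rrp_result <- function(x, ...) {
  cat(sprintf("RRP for %s in [%.3g, %.3g]: %.2f%%%s\n", x$feature, x$ri$low,
              x$ri$high, x$rrp,
              if (x$flagged) " (flagged sub-optimal)" else ""))
  invisible(x)
}

#' Audit reference intervals across follow-up horizons
#'
#' Produces a per-feature-by-horizon table of relative risk percentages.
#' Sex-stratified intervals are evaluated on the matching sex stratum of the
#' evaluation data; horizons without a model are simply absent from the
#' output.
#'
#' @param models named list of fitted models, one per horizon (names like
#'   `"5y"`).
#' @param newdata evaluation [feature_table()] or data.frame.
#' @param intervals list of [reference_interval()]s.
#' @param threshold flag threshold passed to [rrp()].
#' @param sex_feature name of the sex column used for stratified intervals.
#' @return data.frame of class `rrp_audit` with one row per interval and one
#'   RRP column per horizon.
#' @export
audit_intervals <- function(models, newdata, intervals, threshold = 50,
                            sex_feature = "sex") {
  data <- if (inherits(newdata, "feature_table")) newdata$data else as.data.frame(newdata)
  if (inherits(intervals, "reference_interval")) intervals <- list(intervals)
  rows <- lapply(intervals, function(ri) {
    d <- data
    if (!is.na(ri$sex)) {
      if (!sex_feature %in% names(d)) stop_tm("no sex column for a stratified interval")
      d <- d[!is.na(d[[sex_feature]]) & d[[sex_feature]] == ri$sex, , drop = FALSE]
    }
    out <- data.frame(feature = ri$feature, low = ri$low, high = ri$high,
                      sex = ri$sex)
    for (h in names(models)) {
      curve <- relative_risk_curve(models[[h]], d, ri$feature)
      out[[paste0("rrp_", h)]] <- rrp(curve, ri, threshold = threshold)$rrp
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rrp_audit", "data.frame")
  attr(out, "threshold") <- threshold
  out
}
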