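# AUROC point estimation (Mann-Whitney form) and bootstrap evaluation.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half (Mann-Whitney rank form).
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 outcomes.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_tm("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap AUROC evaluation
#'
#' Computes the point AUROC and a percentile 95% interval by resampling
#' subjects with replacement. An optional stratum filter restricts the
#' evaluation (e.g. to one sex); a stratum that loses one of the classes is
#' rejected with an explicit error.
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 outcomes.
#' @param n_boot number of bootstrap replicates.
#' @param seed resampling seed.
#' @param stratum optional logical filter of the same length as `scores`.
#' @param stratum_label optional label stored with the result.
#' @return An object of class `auroc_eval`: list with `auroc`, `ci` (length-2
#'   percentile interval), `boot` (replicate values), `n`, `n_pos`, `n_boot`,
#'   `stratum`.
#' @export
evaluate_auroc <- function(scores, labels, n_boot = 1000, seed = 1L,
                           stratum = NULL, stratum_label = NULL) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop_tm("scores and labels must align")
  if (!is.null(stratum)) {
    scores <- scores[stratum]; labels <- labels[stratum]
  }
  if (length(unique(labels)) < 2L)
    stop_tm("stratum contains a single outcome class; AUROC undefined")
  point <- auroc(scores, labels)
  n <- length(scores)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2L) return(NA_real_)
      auroc(scores[idx], labels[idx])
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(auroc = point, ci = ci, boot = boot, n = n,
                 n_pos = sum(labels == 1L), n_boot = n_boot,
                 stratum = stratum_label),
            class = "auroc_eval")
}

#' @export
print.auroc_eval <- function(x, ...) {
  cat(sprintf("AUROC %.4f (95%% bootstrap CI %.4f-%.4f; n=%d, %d events, %d replicates%s)\n",
              x$auroc, x$ci[1], x$ci[2], x$n, x$n_pos, x$n_boot,
              if (is.null(x$stratum)) "" else paste0("; stratum ", x$stratum)))
  invisible(x)
}
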