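#' Construct a feature table
#'
#' The package's rectangular container: one row per subject, numeric feature
#' columns (missing values allowed and passed natively to tree learners), a
#' role per feature, and an ordinal enrollment cycle per subject for temporal
#' splits.
#'
#' @param data data.frame of numeric feature columns.
#' @param roles named character vector mapping every feature to one of
#'   `"demographic"`, `"examination"`, `"laboratory"`, `"questionnaire"`.
#' @param cycle integer enrollment cycle per subject, or `NULL`.
#' @param id subject identifiers (defaults to `s1..sn`).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(data, roles, cycle = NULL, id = NULL) {
  data <- as.data.frame(data)
  if (anyDuplicated(names(data))) {
    dup <- unique(names(data)[duplicated(names(data))])
    stop_tm("duplicate feature names: ", paste(dup, collapse = ", "))
  }
  bad <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(bad)) stop_tm("non-numeric feature columns: ", paste(bad, collapse = ", "))
  valid_roles <- c("demographic", "examination", "laboratory", "questionnaire")
  if (is.null(names(roles)) || !all(names(data) %in% names(roles)))
    stop_tm("every feature needs a role")
  roles <- roles[names(data)]
  if (!all(roles %in% valid_roles))
    stop_tm("roles must be one of: ", paste(valid_roles, collapse = ", "))
  n <- nrow(data)
  if (!is.null(cycle)) {
    if (length(cycle) != n) stop_tm("cycle must have one entry per subject")
    cycle <- as.integer(cycle)
  }
  if (is.null(id)) id <- paste0("s", seq_len(n))
  structure(list(data = data, roles = roles, cycle = cycle, id = as.character(id)),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$data)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subjects x %d features\n", nrow(x$data), ncol(x$data)))
  tab <- table(x$roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(as.matrix(x$data)))
  cat(sprintf("  missingness: %.1f%%   cycles: %s\n", 100 * miss,
              if (is.null(x$cycle)) "none" else paste(range(x$cycle), collapse = "-")))
  invisible(x)
}

#' Subset a feature table
#'
#' @param ft a [feature_table()].
#' @param rows subject index vector (default all).
#' @param features character vector of features to keep (default all).
#' @return A [feature_table()].
#' @export
ft_subset <- function(ft, rows = NULL, features = NULL) {
  rows <- rows %||% seq_len(nrow(ft$data))
  features <- features %||% names(ft$data)
  missing_f <- setdiff(features, names(ft$data))
  if (length(missing_f)) stop_tm("unknown features: ", paste(missing_f, collapse = ", "))
  feature_table(ft$data[rows, features, drop = FALSE],
                roles = ft$roles[features],
                cycle = if (!is.null(ft$cycle)) ft$cycle[rows],
                id = ft$id[rows])
}

# numeric matrix view used by the learners
ft_matrix <- function(ft, features = NULL) {
  features <- features %||% names(ft$data)
  m <- as.matrix(ft$data[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}
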