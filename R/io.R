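# Cohort readers and writers: plain delimited text plus a JSON sidecar.

#' Write a cohort to delimited text
#'
#' Writes `<stem>.csv` (features, `cycle`, and one `label_<horizon>` column
#' per horizon, `NA` for missing) and `<stem>_meta.json` (feature roles,
#' subject ids, and, for synthetic cohorts, the planted reference
#' intervals).
#'
#' @param ft a [feature_table()].
#' @param path output path for the `.csv` (the sidecar name is derived).
#' @param labels optional label matrix or vector.
#' @param truth optional `ground_truth`; its planted intervals are stored in
#'   the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(ft, path, labels = NULL, truth = NULL) {
  df <- ft$data
  if (!is.null(ft$cycle)) df$cycle <- ft$cycle
  if (!is.null(labels)) {
    labels <- as.matrix(labels)
    if (is.null(colnames(labels))) colnames(labels) <- paste0("h", seq_len(ncol(labels)))
    for (j in seq_len(ncol(labels))) df[[paste0("label_", colnames(labels)[j])]] <- labels[, j]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  meta <- list(roles = as.list(ft$roles), id = ft$id)
  if (!is.null(truth)) {
    meta$reference_intervals <- lapply(truth$reference_intervals, function(ri)
      list(optimal = ri$optimal[c("feature", "low", "high")],
           misset = ri$misset[c("feature", "low", "high")]))
  }
  meta_path <- sub("\\.csv$", "_meta.json", path)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, meta_path))
}

#' Read a cohort from delimited text
#'
#' Reads a header-rowed delimited file into a [feature_table()] plus labels.
#' Missing tokens (`NA`, empty) become missing values; duplicate feature
#' names and non-numeric entries in feature columns are rejected with the
#' offending column and line numbers; per-feature missingness is reported.
#'
#' @param path path to the `.csv`.
#' @param meta_path path to the JSON sidecar with roles (default: derived
#'   from `path`); alternatively supply `roles` directly.
#' @param roles optional named role vector overriding the sidecar.
#' @return List with `table` (a [feature_table()]), `labels` (integer matrix
#'   or `NULL`), and `missingness` (per-feature fraction).
#' @export
read_cohort <- function(path, meta_path = NULL, roles = NULL) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  header <- gsub('^"|"$', "", header)
  if (anyDuplicated(header))
    stop_tm("duplicate column names in ", path, ": ",
            paste(unique(header[duplicated(header)]), collapse = ", "))
  raw <- utils::read.csv(path, check.names = FALSE, na.strings = c("NA", ""),
                         colClasses = "character")
  label_cols <- grep("^label_", header, value = TRUE)
  feat_cols <- setdiff(header, c(label_cols, "cycle"))

  num <- list()
  for (col in c(feat_cols, label_cols, intersect("cycle", header))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad))
      stop_tm(sprintf("non-numeric values in column '%s' at line(s) %s", col,
                      paste(utils::head(bad + 1L, 5), collapse = ", ")))
    num[[col]] <- v
  }
  if (is.null(roles)) {
    meta_path <- meta_path %||% sub("\\.csv$", "_meta.json", path)
    if (file.exists(meta_path)) {
      meta <- jsonlite::read_json(meta_path)
      roles <- unlist(meta$roles)
    } else {
      roles <- stats::setNames(rep("laboratory", length(feat_cols)), feat_cols)
    }
  }
  ft <- feature_table(as.data.frame(num[feat_cols]), roles = roles,
                      cycle = num[["cycle"]])
  labels <- if (length(label_cols)) {
    m <- do.call(cbind, num[label_cols])
    colnames(m) <- sub("^label_", "", label_cols)
    storage.mode(m) <- "integer"
    m
  }
  missingness <- vapply(ft$data, function(v) mean(is.na(v)), numeric(1))
  list(table = ft, labels = labels, missingness = missingness)
}
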