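#' Patients-by-features table with signal-family group tags
#'
#' A `feature_table` is a data.frame holding one row per patient: an `id`
#' column, the binary Echo-LVH label (`lvh`, 0/1), optional metadata columns
#' (covariates, `split`), and numeric feature columns. Each feature column
#' carries a group tag, `"VCG"` or `"ECG"`, stored in the `groups` attribute;
#' lasso pruning is applied separately per group.
#'
#' @param df data.frame containing at least `lvh` and the tagged columns.
#' @param groups named character vector mapping feature column names to
#'   `"VCG"` or `"ECG"`.
#' @param label label column name (default `"lvh"`).
#' @return the data.frame with class `feature_table` and attribute `groups`.
#' @export
feature_table <- function(df, groups, label = "lvh") {
  stopifnot(is.data.frame(df))
  if (!label %in% names(df)) stop("label column '", label, "' missing")
  lab <- df[[label]]
  if (any(is.na(lab))) stop("labels must be present for all rows")
  if (!all(lab %in% c(0, 1))) stop("labels must be 0/1")
  if (is.null(names(groups)) || !all(names(groups) %in% names(df)))
    stop("groups must be named after existing columns")
  if (!all(groups %in% c("VCG", "ECG")))
    stop("group tags must be 'VCG' or 'ECG'")
  for (nm in names(groups))
    if (!is.numeric(df[[nm]])) stop("feature column ", nm, " is not numeric")
  all_na <- vapply(names(groups), function(nm) all(is.na(df[[nm]])),
                   logical(1L))
  if (any(all_na))
    stop("feature column(s) entirely missing: ",
         paste(names(groups)[all_na], collapse = ", "))
  structure(df, groups = groups, label = label,
            class = c("feature_table", "data.frame"))
}

#' Feature columns of a table, optionally restricted to one group
#' @param t a [feature_table()].
#' @param group `NULL` (all features), `"VCG"` or `"ECG"`.
#' @return character vector of column names.
#' @export
feature_names <- function(t, group = NULL) {
  g <- attr(t, "groups")
  if (is.null(group)) names(g) else names(g)[g == group]
}

#' Assign a random train/test split
#'
#' Adds (or replaces) a `split` column with values `"train"`/`"test"` drawn
#' by simple random allocation at the given training proportion.
#'
#' @param t a [feature_table()].
#' @param prop training fraction (default 0.7).
#' @param seed optional integer seed.
#' @return the table with a `split` column.
#' @export
assign_split <- function(t, prop = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(t)
  n_train <- round(prop * n)
  idx <- sample.int(n, n_train)
  t$split <- "test"
  t$split[idx] <- "train"
  t
}

#' Write a feature table to CSV with a group header line
#'
#' Line 1 is a comment of the form `#group,<tag>,<tag>,...` giving the group
#' of each column (empty for non-feature columns); the remainder is a
#' standard CSV.
#'
#' @param t a [feature_table()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path) {
  g <- attr(t, "groups")
  tags <- ifelse(names(t) %in% names(g), g[names(t)], "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#group", tags), collapse = ","), con)
  utils::write.csv(as.data.frame(t), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Reads the dialect of [write_feature_table()]. Plain labeled CSVs without
#' a group line (such as an externally exported feature dataset) are also
#' accepted by supplying `group_map`, a named vector tagging the feature
#' columns; untagged columns are treated as metadata.
#'
#' @param path file path.
#' @param label label column name (default `"lvh"`).
#' @param group_map optional named character vector of group tags used when
#'   the file has no `#group` line.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, label = "lvh", group_map = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#group")) {
    tags <- strsplit(first, ",", fixed = TRUE)[[1L]][-1L]
    df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
    if (length(tags) != ncol(df)) stop("group line does not match columns")
    groups <- stats::setNames(tags, names(df))
    groups <- groups[nzchar(groups)]
  } else {
    if (is.null(group_map))
      stop("file has no #group line; supply group_map")
    df <- utils::read.csv(path, check.names = FALSE)
    groups <- group_map
  }
  feature_table(df, groups = groups, label = label)
}
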