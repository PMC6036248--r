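## FeatureTable: a data.frame with metadata columns first
## (row_id, subject, day, class, epoch) and non-negative band-power
## feature columns after them. The unit everything downstream consumes.

META_COLS <- c("row_id", "subject", "day", "class", "epoch")

#' Construct a feature table
#'
#' A feature table holds one row per 5-s epoch: metadata columns
#' (`row_id`, `subject`, `day`, `class`, `epoch`) followed by one
#' non-negative band-power column per (channel, band) pair in
#' channel-major order.
#'
#' @param features numeric matrix, epochs x features, with column names
#'   following the `"<channel>_<band>"` convention.
#' @param subject subject identifier (recycled).
#' @param day integer day index per row (recycled).
#' @param class class label per row (recycled).
#' @param epoch optional within-(day, class) temporal epoch index; defaults
#'   to the running index within each (day, class) cell.
#' @param row_id optional unique row identifiers; autogenerated when `NULL`.
#' @return a `feature_table` (also a plain `data.frame`).
#' @seealso [feature_cols()], [feature_matrix()], [subject_study()]
#' @export
feature_table <- function(features, subject, day, class, epoch = NULL,
                          row_id = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    stop("feature matrix must have column names")
  n <- nrow(features)
  meta <- data.frame(
    subject = rep_len(subject, n),
    day = rep_len(as.integer(day), n),
    class = rep_len(as.character(class), n),
    stringsAsFactors = FALSE
  )
  if (is.null(epoch)) {
    epoch <- stats::ave(seq_len(n), meta$day, meta$class, FUN = seq_along)
  }
  meta$epoch <- rep_len(as.integer(epoch), n)
  if (is.null(row_id)) {
    row_id <- sprintf("s%s_d%d_%s_e%d", meta$subject, meta$day,
                      meta$class, meta$epoch)
  }
  out <- cbind(data.frame(row_id = as.character(row_id),
                          stringsAsFactors = FALSE),
               meta, as.data.frame(features))
  validate_feature_table(out)
}

validate_feature_table <- function(x) {
  stopifnot(is.data.frame(x), all(META_COLS %in% names(x)))
  fc <- setdiff(names(x), META_COLS)
  if (length(fc) == 0L) stop("feature table has no feature columns")
  fm <- as.matrix(x[fc])
  if (!is.numeric(fm) || any(!is.finite(fm)))
    stop("feature values must be finite numerics")
  if (any(fm < 0))
    stop("band powers must be non-negative")
  if (anyDuplicated(x$row_id))
    stop("row_id values must be unique")
  rownames(x) <- NULL
  class(x) <- unique(c("feature_table", class(x)))
  x
}

#' @rdname feature_table
#' @param x a feature table.
#' @export
feature_cols <- function(x) setdiff(names(x), META_COLS)

#' @rdname feature_table
#' @export
feature_matrix <- function(x) {
  m <- as.matrix(x[feature_cols(x)])
  rownames(m) <- x$row_id
  m
}

#' Restrict a feature table to a subset of feature columns
#'
#' @param x a feature table.
#' @param features character vector of feature column names to keep.
#' @return a feature table with only the requested feature columns,
#'   metadata untouched.
#' @export
select_features <- function(x, features) {
  missing <- setdiff(features, feature_cols(x))
  if (length(missing))
    stop("unknown feature columns: ", paste(missing, collapse = ", "))
  out <- x[c(META_COLS, features)]
  class(out) <- class(x)
  out
}

rbind_feature_tables <- function(tables) {
  out <- do.call(rbind, lapply(tables, function(t) {
    class(t) <- "data.frame"
    t
  }))
  rownames(out) <- NULL
  class(out) <- c("feature_table", class(out))
  out
}

#' Bundle the per-day feature tables of one subject
#'
#' A subject study is the unit the calibration protocols consume: the
#' five per-day feature tables of one subject, with consistent feature
#' columns and all three classes present on every day.
#'
#' @param x a feature table covering all days of one subject, or a list
#'   of per-day feature tables.
#' @param n_days required number of days (default 5).
#' @param check_classes require every class on every day (default TRUE).
#' @return a `subject_study`: a named list of per-day feature tables
#'   (names are the day indices as characters).
#' @export
subject_study <- function(x, n_days = 5L, check_classes = TRUE) {
  if (is.data.frame(x)) {
    days <- split(x, x$day)
    days <- lapply(days, function(d) {
      rownames(d) <- NULL
      class(d) <- class(x)
      d
    })
  } else {
    days <- x
    names(days) <- vapply(days, function(d) as.character(d$day[1]), "")
  }
  if (length(days) != n_days)
    stop("expected ", n_days, " days, got ", length(days))
  fc <- feature_cols(days[[1]])
  for (d in days) {
    if (!identical(feature_cols(d), fc))
      stop("inconsistent feature columns across days")
    if (check_classes && length(unique(d$class)) < 3L)
      stop("each day must contain all 3 classes")
  }
  structure(days, class = "subject_study")
}

#' @export
print.subject_study <- function(x, ...) {
  cat("<subject_study> ", length(x), " days, ",
      length(feature_cols(x[[1]])), " features\n", sep = "")
  for (nm in names(x))
    cat("  day ", nm, ": ", nrow(x[[nm]]), " epochs (",
        paste(sprintf("%s=%d", names(table(x[[nm]]$class)),
                      as.integer(table(x[[nm]]$class))), collapse = ", "),
        ")\n", sep = "")
  invisible(x)
}

#' Study accessors
#'
#' `study_day_counts` gives per-day row counts, `study_features` the
#' shared feature columns, `study_select_features` restricts every day
#' to a feature subset, and `study_row_ids` collects all row ids.
#'
#' @param study a [subject_study()].
#' @param features character vector of feature columns to keep.
#' @name study-accessors
NULL

#' @rdname study-accessors
#' @export
study_day_counts <- function(study) vapply(study, nrow, 0L)

#' @rdname study-accessors
#' @export
study_features <- function(study) feature_cols(study[[1]])

#' @rdname study-accessors
#' @export
study_select_features <- function(study, features) {
  structure(lapply(study, select_features, features = features),
            class = "subject_study")
}

#' @rdname study-accessors
#' @export
study_row_ids <- function(study) {
  unlist(lapply(study, `[[`, "row_id"), use.names = FALSE)
}
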