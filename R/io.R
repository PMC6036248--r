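## Delimited-text serialization: feature tables, tidy protocol results,
## epoch arrays with a JSON metadata sidecar, CR grids.

#' Write / read a feature table as delimited text
#'
#' One epoch per row, header row, metadata columns first
#' (`row_id, subject, day, class, epoch`), then the feature columns.
#'
#' @param x a [feature_table()] or a `subject_study` (days are
#'   concatenated).
#' @param path output file.
#' @param sep field separator (default `,`; use `"\t"` for TSV).
#' @return `read_feature_table` returns a `feature_table`;
#'   `read_subject_study` additionally splits it into a
#'   [subject_study()].
#' @export
write_feature_table <- function(x, path, sep = ",") {
  if (inherits(x, "subject_study")) x <- rbind_feature_tables(x)
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE,
                         check.names = FALSE)
  validate_feature_table(x)
}

#' @rdname write_feature_table
#' @param n_days expected day count for the study (default 5).
#' @export
read_subject_study <- function(path, sep = ",", n_days = 5L) {
  subject_study(read_feature_table(path, sep), n_days = n_days)
}

#' Write a protocol result as tidy delimited text
#'
#' One row per accuracy cell with its train/test annotations, plus a
#' JSON sidecar (`<path>.meta.json`) echoing the protocol, repetition
#' count, seed, classifier configuration and its content hash.
#'
#' @param result a `protocol_result` (or `lndi_result`).
#' @param path output file for the cell table.
#' @param sep field separator.
#' @return the path, invisibly.
#' @export
write_protocol_result <- function(result, path, sep = ",") {
  utils::write.table(result$cells, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  meta <- list(protocol = result$protocol,
               mean_accuracy = result$mean_accuracy,
               repetitions = result$repetitions, seed = result$seed,
               N = result$N, classifier = unclass(result$cfg),
               config_hash = config_hash(unclass(result$cfg)))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write epoch arrays as plain text with a metadata sidecar
#'
#' Each epoch is written as `<prefix>_<k>.csv` (channels x samples, one
#' channel per row, channel name in the first column) and a single
#' `<prefix>_meta.json` records fs, channel names and per-epoch
#' (subject, day, class, epoch) metadata.
#'
#' @param epochs list of [epoch_array()]s.
#' @param prefix path prefix for the output files.
#' @return the metadata path, invisibly.
#' @export
write_epoch_arrays <- function(epochs, prefix) {
  meta <- list(fs = epochs[[1]]$fs,
               channel_names = epochs[[1]]$channel_names,
               epochs = list())
  for (k in seq_along(epochs)) {
    ep <- epochs[[k]]
    df <- data.frame(channel = ep$channel_names, ep$data,
                     check.names = FALSE)
    utils::write.table(df, sprintf("%s_%d.csv", prefix, k), sep = ",",
                       row.names = FALSE, quote = FALSE)
    meta$epochs[[k]] <- list(file = basename(sprintf("%s_%d.csv", prefix, k)),
                             subject = ep$subject, day = ep$day,
                             class = ep$class, epoch = ep$epoch)
  }
  meta_path <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta_path)
}

#' @rdname write_epoch_arrays
#' @export
read_epoch_arrays <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  dir <- dirname(prefix)
  lapply(seq_len(nrow(meta$epochs)), function(k) {
    df <- utils::read.table(file.path(dir, meta$epochs$file[k]),
                            header = TRUE, sep = ",", check.names = FALSE)
    epoch_array(as.matrix(df[-1]), fs = meta$fs,
                channel_names = df$channel,
                subject = meta$epochs$subject[k],
                day = meta$epochs$day[k],
                class = meta$epochs$class[k],
                epoch = meta$epochs$epoch[k])
  })
}

#' Write a contribution-rate grid as a labeled table
#'
#' @param cr matrix from [contribution_rates()].
#' @param path output file.
#' @param sep field separator.
#' @export
write_contribution_rates <- function(cr, path, sep = ",") {
  df <- data.frame(channel = rownames(cr), cr, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
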