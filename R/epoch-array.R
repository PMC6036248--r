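#' Construct a multichannel epoch
#'
#' An epoch array is one 5-s (by default) window of multichannel EEG:
#' a channels x time-samples matrix plus sampling rate, ordered channel
#' names and (subject, day, class, epoch) metadata.
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_names ordered channel labels, one per row of `data`.
#' @param subject,day,class,epoch metadata scalars.
#' @return an `epoch_array`.
#' @export
epoch_array <- function(data, fs, channel_names = rownames(data),
                        subject = NA, day = NA_integer_,
                        class = NA_character_, epoch = NA_integer_) {
  data <- as.matrix(data)
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel count must match channel_names length")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs,
                 channel_names = as.character(channel_names),
                 subject = subject, day = as.integer(day),
                 class = as.character(class), epoch = as.integer(epoch)),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat("<epoch_array> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", ncol(x$data) / x$fs, " s)",
      if (!is.na(x$day)) sprintf("; subject %s day %d class %s epoch %d",
                                 x$subject, x$day, x$class, x$epoch),
      "\n", sep = "")
  invisible(x)
}

validate_epoch <- function(epoch, epoch_seconds = NULL) {
  stopifnot(inherits(epoch, "epoch_array"))
  if (!is.null(epoch_seconds) &&
      ncol(epoch$data) != round(epoch$fs * epoch_seconds))
    stop("time-sample count must equal fs x epoch_seconds")
  invisible(epoch)
}
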