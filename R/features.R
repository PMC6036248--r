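## Preprocessing and Welch band-power feature extraction.
## Conventions: 500-ms Hamming segments at 50% overlap, mean-detrended;
## band power = integral of one-sided density over half-open [f_low,
## f_high) intervals; feature columns channel-major "CH{i}_{band}".

#' Welch estimator configuration
#'
#' @param window_seconds segment length in seconds (default 0.5; for a
#'   5-s epoch this yields 19 half-overlapping segments).
#' @param overlap_fraction fraction of segment overlap in `[0, 1)`
#'   (default 0.5).
#' @param taper `"hamming"` (default) or `"rectangular"`.
#' @param detrend remove each segment's mean before tapering
#'   (default TRUE).
#' @return a `welch_config` list.
#' @export
welch_config <- function(window_seconds = 0.5, overlap_fraction = 0.5,
                         taper = c("hamming", "rectangular"),
                         detrend = TRUE) {
  taper <- match.arg(taper)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (window_seconds <= 0) stop("window_seconds must be positive")
  structure(list(window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction,
                 taper = taper, detrend = detrend),
            class = "welch_config")
}

#' Re-reference an epoch to the mean of reference channels
#'
#' Subtracts the mean of the named reference channels (e.g. the two
#' mastoids) from every other channel and drops the reference channels
#' from the output.
#'
#' @param epoch an [epoch_array()].
#' @param reference_channels character vector of reference channel names.
#' @return re-referenced `epoch_array` without the reference channels.
#' @export
rereference <- function(epoch, reference_channels) {
  validate_epoch(epoch)
  missing <- setdiff(reference_channels, epoch$channel_names)
  if (length(missing))
    stop("unknown reference channel(s): ", paste(missing, collapse = ", "))
  ref_idx <- match(reference_channels, epoch$channel_names)
  ref <- colMeans(epoch$data[ref_idx, , drop = FALSE])
  keep <- setdiff(seq_along(epoch$channel_names), ref_idx)
  data <- sweep(epoch$data[keep, , drop = FALSE], 2, ref, `-`)
  epoch_array(data, fs = epoch$fs,
              channel_names = epoch$channel_names[keep],
              subject = epoch$subject, day = epoch$day,
              class = epoch$class, epoch = epoch$epoch)
}

#' Decimate an epoch to a lower sampling rate
#'
#' Applies an exact frequency-domain anti-alias low-pass (zeroing all
#' content at or above the new Nyquist) and keeps every `fs/target_fs`-th
#' sample. `target_fs` must divide `fs`.
#'
#' @param epoch an [epoch_array()].
#' @param target_fs new sampling rate in Hz.
#' @return decimated `epoch_array` with `fs = target_fs`.
#' @export
decimate <- function(epoch, target_fs) {
  validate_epoch(epoch)
  if (target_fs == epoch$fs) return(epoch)
  r <- epoch$fs / target_fs
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop("target_fs must divide fs (non-integer decimation ratio)")
  r <- round(r)
  n <- ncol(epoch$data)
  f <- (seq_len(n) - 1) * epoch$fs / n
  f_mirror <- pmin(f, epoch$fs - f)
  keep <- f_mirror < target_fs / 2
  data <- t(apply(epoch$data, 1, function(x) {
    X <- stats::fft(x)
    X[!keep] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  }))
  data <- data[, seq(1, n, by = r), drop = FALSE]
  epoch_array(data, fs = target_fs, channel_names = epoch$channel_names,
              subject = epoch$subject, day = epoch$day,
              class = epoch$class, epoch = epoch$epoch)
}

## One-sided Welch power spectral density of a single signal.
## Returns list(freq, psd) with density in power / Hz; integrating
## psd * df over all bins recovers (approximately) the signal power.
welch_psd <- function(x, fs, cfg = welch_config()) {
  nper <- round(cfg$window_seconds * fs)
  if (nper < 2) stop("window too short")
  if (length(x) < nper) stop("epoch shorter than the Welch window")
  step <- max(1L, round(nper * (1 - cfg$overlap_fraction)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- if (cfg$taper == "hamming") {
    0.54 - 0.46 * cos(2 * pi * (0:(nper - 1)) / (nper - 1))
  } else rep(1, nper)
  scale <- fs * sum(w^2)
  n_keep <- nper %/% 2 + 1L
  acc <- numeric(n_keep)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    if (cfg$detrend) seg <- seg - mean(seg)
    P <- abs(stats::fft(seg * w))^2 / scale
    P <- P[seq_len(n_keep)]
    # one-sided: double everything except DC and (even nper) Nyquist
    dbl <- rep(2, n_keep)
    dbl[1] <- 1
    if (nper %% 2 == 0) dbl[n_keep] <- 1
    acc <- acc + P * dbl
  }
  list(freq = (seq_len(n_keep) - 1) * fs / nper,
       psd = acc / length(starts),
       df = fs / nper)
}

## Direct periodogram of the full epoch (rectangular window): the
## independent spectral oracle used by the test suite.
periodogram_psd <- function(x, fs) {
  n <- length(x)
  n_keep <- n %/% 2 + 1L
  P <- abs(stats::fft(x))^2 / (fs * n)
  P <- P[seq_len(n_keep)]
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_keep] <- 1
  list(freq = (seq_len(n_keep) - 1) * fs / n, psd = P * dbl, df = fs / n)
}

## Integrate a PSD over half-open band intervals [f_low, f_high).
integrate_bands <- function(spec, bands) {
  vapply(seq_len(nrow(bands)), function(b) {
    sel <- spec$freq >= bands$f_low[b] & spec$freq < bands$f_high[b]
    sum(spec$psd[sel]) * spec$df
  }, 0)
}

#' Welch band powers of a multichannel epoch
#'
#' Estimates each channel's power spectral density by Welch's method
#' (averaged tapered overlapping periodograms) and integrates it over
#' each band's half-open `[f_low, f_high)` interval.
#'
#' @param epoch an [epoch_array()].
#' @param cfg a [welch_config()].
#' @param bands a band scheme, see [default_bands()].
#' @return channels x bands matrix of non-negative band powers with
#'   dimnames `(channel_names, band names)`.
#' @export
welch_band_powers <- function(epoch, cfg = welch_config(),
                              bands = default_bands()) {
  validate_epoch(epoch)
  if (max(bands$f_high) > epoch$fs / 2)
    stop("band edge above Nyquist frequency")
  out <- t(apply(epoch$data, 1, function(x) {
    integrate_bands(welch_psd(x, epoch$fs, cfg), bands)
  }))
  dimnames(out) <- list(epoch$channel_names, bands$name)
  out
}

#' Optional artifact-removal hook
#'
#' Placeholder for ocular-artifact removal (e.g. ICA-based) in real
#' recordings. The default implementation is the identity: synthetic
#' epochs carry no ocular artifacts, so the pipeline exposes the hook
#' without prescribing a method.
#'
#' @param epoch an [epoch_array()].
#' @param method only `"none"` is built in.
#' @return the (possibly cleaned) `epoch_array`.
#' @export
remove_artifacts <- function(epoch, method = "none") {
  validate_epoch(epoch)
  if (!identical(method, "none"))
    stop("no artifact-removal backend built in; got method = ", method)
  epoch
}

#' Extract a band-power feature table from epochs
#'
#' Computes Welch band powers for every epoch and assembles the feature
#' table: one row per epoch, `n_channels * n_bands` feature columns in
#' channel-major order (360 for 60 channels and 6 bands), metadata
#' propagated from the epochs. Epochs may list channels in any order;
#' columns are aligned by channel name to the first epoch's ordering.
#'
#' @param epochs list of [epoch_array()]s with identical channel sets.
#' @param cfg a [welch_config()].
#' @param bands a band scheme.
#' @return a [feature_table()].
#' @export
extract_features <- function(epochs, cfg = welch_config(),
                             bands = default_bands()) {
  stopifnot(length(epochs) >= 1L)
  ref_channels <- epochs[[1]]$channel_names
  fnames <- feature_names(ref_channels, bands)
  rows <- matrix(0, length(epochs), length(fnames),
                 dimnames = list(NULL, fnames))
  meta <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    if (!setequal(ep$channel_names, ref_channels))
      stop("inconsistent channel names across epochs")
    bp <- welch_band_powers(ep, cfg, bands)
    # align to the canonical channel order by name
    bp <- bp[ref_channels, , drop = FALSE]
    rows[i, ] <- as.vector(t(bp))
    meta[[i]] <- list(subject = ep$subject, day = ep$day,
                      class = ep$class, epoch = ep$epoch)
  }
  feature_table(rows,
                subject = unlist(lapply(meta, `[[`, "subject")),
                day = unlist(lapply(meta, `[[`, "day")),
                class = unlist(lapply(meta, `[[`, "class")),
                epoch = unlist(lapply(meta, `[[`, "epoch")))
}
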