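## Signal-level generator: synthesizes raw multichannel epochs whose
## band powers realize the same log-linear model as the feature-level
## path. Band-limited components are built by frequency-domain masking
## of white Gaussian noise (exact band confinement, no filter leakage),
## then scaled so the realized band power equals the target exactly.

#' Generate a multi-day signal-level study for one subject
#'
#' Draws per-epoch target band powers from the same log-linear model as
#' [generate_feature_study()] and synthesizes, for each channel, a raw
#' signal that is the sum over bands of independent band-limited
#' Gaussian noise scaled so its band power equals the target. Running
#' [extract_features()] over the result recovers (up to Welch estimation
#' error) the feature-level study of the same seed and subject.
#'
#' @param model a [synthetic_model()].
#' @param subject_id subject identifier.
#' @param days integer vector of days to generate (default all; signal
#'   synthesis is much heavier than the feature path).
#' @param reference_channels if `TRUE`, append two synthetic mastoid
#'   channels `M1`, `M2` carrying a shared common-mode signal that is
#'   also added to every data channel, so [rereference()] can be
#'   exercised end to end.
#' @param common_mode_sd amplitude (sd) of the common-mode signal when
#'   `reference_channels` is used.
#' @return list of [epoch_array()]s in (day, class-block, epoch) order.
#' @export
generate_signal_study <- function(model, subject_id = 1L, days = NULL,
                                  reference_channels = FALSE,
                                  common_mode_sd = 5) {
  stopifnot(inherits(model, "synthetic_model"))
  if (max(model$bands$f_high) > model$fs / 2)
    stop("band edge at or above Nyquist")
  days <- days %||% seq_len(model$n_days)
  # identical target draw as the feature path (same derived seed)
  study <- withr::with_seed(derive_seed(model$seed, "feature", subject_id),
                            realization_study(model, subject_id))
  n <- round(model$fs * model$epoch_seconds)
  out <- list()
  withr::with_seed(derive_seed(model$seed, "signal", subject_id), {
    for (d in days) {
      tab <- study[[as.character(d)]]
      targets <- feature_matrix(tab)
      for (r in seq_len(nrow(tab))) {
        tgt <- matrix(targets[r, ], nrow = model$n_channels,
                      byrow = TRUE)  # channels x bands (channel-major cols)
        sig <- matrix(0, model$n_channels, n)
        for (c_i in seq_len(model$n_channels)) {
          sig[c_i, ] <- synth_multiband(tgt[c_i, ], model$bands, model$fs, n)
        }
        ch_names <- model$channel_names
        if (reference_channels) {
          cm <- stats::rnorm(n, 0, common_mode_sd)
          sig <- rbind(sig + rep(cm, each = model$n_channels),
                       matrix(cm, 2, n, byrow = TRUE))
          ch_names <- c(ch_names, "M1", "M2")
        }
        out[[length(out) + 1L]] <- epoch_array(
          sig, fs = model$fs, channel_names = ch_names,
          subject = subject_id, day = d, class = tab$class[r],
          epoch = tab$epoch[r])
      }
    }
  })
  out
}

## One channel: sum over bands of band-limited Gaussian noise with band
## power scaled exactly to `targets[b]` (variance units). Zero target
## gives a zero component.
synth_multiband <- function(targets, bands, fs, n) {
  x <- numeric(n)
  for (b in seq_len(nrow(bands))) {
    if (targets[b] <= 0) next
    x <- x + band_limited_noise(bands$f_low[b], bands$f_high[b],
                                fs, n, targets[b])
  }
  x
}

band_limited_noise <- function(f_low, f_high, fs, n, power) {
  if (f_high > fs / 2) stop("band edge at or above Nyquist")
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  # two-sided mask over [f_low, f_high), mirrored onto negative freqs
  f_mirror <- pmin(f, fs - f)
  keep <- f_mirror >= f_low & f_mirror < f_high
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  p <- mean(x^2)
  if (p <= 0) return(numeric(n))
  x * sqrt(power / p)
}
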