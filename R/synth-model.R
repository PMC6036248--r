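## Synthetic multi-day EEG world: a log-linear band-power model
##   log10 P(epoch, channel, band) = beta + gamma_class + delta_day + eps
## with gamma nonzero only on a sparse informative set and zero-mean over
## classes, delta drawn N(0, sigma_day^2) fresh per realization (or fixed),
## and eps ~ N(0, sigma^2) i.i.d. per (epoch, channel, band).

#' Specify a synthetic multi-day EEG model
#'
#' Defines the generative world for multi-day, multi-subject EEG band
#' powers: a baseline log10 power surface over (channel, band), a
#' class-effect tensor that is nonzero only on a sparse informative set
#' and sums to zero over classes, day-effect offsets drawn
#' `Normal(0, day_sd^2)` once per realization (or fixed via
#' `day_effect`), optional slow within-day drift, and i.i.d. epoch noise.
#' Both the feature-level generator ([generate_feature_study()]) and the
#' signal-level generator ([generate_signal_study()]) draw from this
#' same model, so they agree in expectation.
#'
#' @param n_channels number of EEG channels (default 60).
#' @param n_days number of recording days per subject (default 5).
#' @param classes ordered emotion class labels (default positive,
#'   neutral, negative).
#' @param fs sampling rate in Hz (default 500).
#' @param epoch_seconds epoch duration in seconds (default 5).
#' @param epochs_per_day_per_class integer vector, one entry per day,
#'   giving the epoch count per class on that day (may be unequal across
#'   days). Default `c(30, 40, 34, 36, 44)` (day totals 90..132).
#' @param bands band scheme, see [default_bands()].
#' @param baseline channels x bands matrix of baseline log10 band powers;
#'   default is a 1/f-like per-band profile replicated over channels.
#' @param class_effect optional classes x channels x bands array; must be
#'   zero-mean over classes everywhere and zero outside the informative
#'   set. Built from `informative`/`effect_size` when `NULL`.
#' @param informative data frame with columns `channel`, `band` (integer
#'   indices) listing the informative (channel, band) pairs; default: 8
#'   pairs concentrated on the gamma bands of spread-out channels.
#' @param effect_size class-effect magnitude in log10 units (default 0.5).
#' @param day_sd standard deviation of day offsets, log10 units
#'   (default 0.15).
#' @param day_effect optional fixed days x channels x bands array of day
#'   offsets (regression-test mode); when `NULL`, offsets are drawn fresh
#'   per realization.
#' @param day_effect_on `"all"` (default) or `"noninformative"`: restrict
#'   day offsets to non-informative (channel, band) pairs, which isolates
#'   drift to nuisance features.
#' @param day_sd_informative optional separate day-offset sd for the
#'   informative pairs (default `NULL`: same `day_sd` everywhere).
#'   Day-dependent and emotion-related features need not drift equally;
#'   a small value here with a large `day_sd` models nuisance-dominated
#'   drift while keeping the class signal stable across days.
#' @param noise_sd per-epoch log10-power noise sd (default 0.2).
#' @param within_day_drift_sd sd of a per-(day, channel, band) linear
#'   drift slope applied over the temporal epoch order within a day
#'   (default 0: no within-day drift).
#' @param seed master integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return a `synthetic_model` list.
#' @examples
#' m <- synthetic_model(n_channels = 4, epochs_per_day_per_class = rep(8, 5))
#' study <- generate_feature_study(m, subject_id = 1)
#' study
#' @export
synthetic_model <- function(n_channels = 60L, n_days = 5L,
                            classes = c("positive", "neutral", "negative"),
                            fs = 500, epoch_seconds = 5,
                            epochs_per_day_per_class = c(30L, 40L, 34L, 36L, 44L),
                            bands = default_bands(),
                            baseline = NULL,
                            class_effect = NULL,
                            informative = NULL,
                            effect_size = 0.5,
                            day_sd = 0.15,
                            day_effect = NULL,
                            day_effect_on = c("all", "noninformative"),
                            day_sd_informative = NULL,
                            noise_sd = 0.2,
                            within_day_drift_sd = 0,
                            seed = 1L) {
  day_effect_on <- match.arg(day_effect_on)
  bands <- validate_bands(bands)
  nb <- n_bands(bands)
  if (!is_count(n_channels)) stop("n_channels must be a positive count")
  if (!is_count(n_days)) stop("n_days must be a positive count")
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (length(epochs_per_day_per_class) == 1L)
    epochs_per_day_per_class <- rep(epochs_per_day_per_class, n_days)
  if (length(epochs_per_day_per_class) != n_days ||
      !all(vapply(epochs_per_day_per_class, is_count, TRUE)))
    stop("epochs_per_day_per_class must be ", n_days, " counts >= 1")
  if (!is.finite(fs) || fs <= 2 * max(bands$f_high))
    stop("fs must exceed twice the highest band edge")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be finite >= 0")
  if (!is.finite(day_sd) || day_sd < 0) stop("day_sd must be finite >= 0")
  if (!is.null(day_sd_informative) &&
      (!is.finite(day_sd_informative) || day_sd_informative < 0))
    stop("day_sd_informative must be finite >= 0")
  if (!is.finite(within_day_drift_sd) || within_day_drift_sd < 0)
    stop("within_day_drift_sd must be finite >= 0")

  channel_names <- paste0("CH", seq_len(n_channels))

  if (is.null(baseline)) {
    # typical resting log10 band powers (uV^2), 1/f-like decay over bands
    profile <- c(1.5, 1.0, 1.1, 0.7, 0.2, 0.0)[seq_len(min(nb, 6L))]
    if (nb > 6L) profile <- c(profile, rep(0, nb - 6L))
    baseline <- matrix(rep(profile, each = n_channels), n_channels, nb)
  }
  baseline <- as.matrix(baseline)
  if (!all(dim(baseline) == c(n_channels, nb)) || any(!is.finite(baseline)))
    stop("baseline must be a finite ", n_channels, " x ", nb, " matrix")
  dimnames(baseline) <- list(channel_names, bands$name)

  if (is.null(informative) && is.null(class_effect)) {
    informative <- default_informative_set(n_channels, bands)
  }
  if (is.null(class_effect)) {
    class_effect <- class_effect_tensor(classes, n_channels, bands,
                                        informative, effect_size)
  }
  class_effect <- validate_class_effect(class_effect, classes,
                                        n_channels, bands)
  informative <- informative_pairs(class_effect)

  if (!is.null(day_effect)) {
    day_effect <- array(day_effect, dim = c(n_days, n_channels, nb))
    if (any(!is.finite(day_effect))) stop("day_effect must be finite")
  }

  structure(list(
    n_channels = as.integer(n_channels), n_days = as.integer(n_days),
    classes = classes, fs = fs, epoch_seconds = epoch_seconds,
    epochs_per_day_per_class = as.integer(epochs_per_day_per_class),
    bands = bands, channel_names = channel_names,
    baseline = baseline, class_effect = class_effect,
    informative = informative, day_sd = day_sd, day_effect = day_effect,
    day_effect_on = day_effect_on,
    day_sd_informative = day_sd_informative, noise_sd = noise_sd,
    within_day_drift_sd = within_day_drift_sd,
    seed = as.integer(seed)
  ), class = "synthetic_model")
}

## Default sparse informative set: 8 pairs biased to the gamma bands
## (mirrors the gamma dominance typically reported for emotion features),
## on channels spread across the montage.
default_informative_set <- function(n_channels, bands) {
  nb <- n_bands(bands)
  ch <- unique(pmax(1L, round(seq(1, n_channels, length.out = 8))))
  ch <- rep_len(ch, 8L)
  gamma <- which(grepl("gamma", bands$name))
  if (length(gamma) == 0L) gamma <- nb
  bd <- rep_len(gamma, 8L)
  data.frame(channel = as.integer(ch), band = as.integer(bd))
}

## Balanced class-effect tensor: informative pair j gets a distinct
## zero-mean direction over the 3 classes. Zero-mean 3-vectors live in
## a 2-D plane; the J informative pairs take J equally spaced unit
## directions in that plane (scaled to the norm of the reference
## pattern (1, 0, -1)), so each informative feature carries a distinct
## slice of class information rather than duplicating a few patterns.
class_effect_tensor <- function(classes, n_channels, bands, informative,
                                effect_size) {
  nb <- n_bands(bands)
  nc <- length(classes)
  gamma <- array(0, dim = c(nc, n_channels, nb))
  J <- nrow(informative)
  if (J == 0L) return(gamma)
  u1 <- c(1, 0, -1) / sqrt(2)
  u2 <- c(1, -2, 1) / sqrt(6)
  for (j in seq_len(J)) {
    theta <- 2 * pi * (j - 1) / J
    p <- rep_len(cos(theta) * u1 + sin(theta) * u2, nc)
    p <- (p - mean(p)) * sqrt(2)   # norm of the (1, 0, -1) reference
    gamma[, informative$channel[j], informative$band[j]] <- p * effect_size
  }
  gamma
}

validate_class_effect <- function(gamma, classes, n_channels, bands) {
  nb <- n_bands(bands)
  gamma <- array(gamma, dim = c(length(classes), n_channels, nb))
  if (any(!is.finite(gamma))) stop("class_effect must be finite")
  mns <- apply(gamma, c(2, 3), mean)
  if (max(abs(mns)) > 1e-8)
    stop("class_effect must average to zero over classes per (channel, band)")
  gamma
}

informative_pairs <- function(gamma) {
  nz <- apply(gamma != 0, c(2, 3), any)
  idx <- which(nz, arr.ind = TRUE)
  data.frame(channel = as.integer(idx[, 1]), band = as.integer(idx[, 2]))
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat("<synthetic_model> ", x$n_channels, " channels x ", n_bands(x$bands),
      " bands, ", x$n_days, " days, classes: ",
      paste(x$classes, collapse = "/"), "\n", sep = "")
  cat("  epochs/day/class: ",
      paste(x$epochs_per_day_per_class, collapse = ", "),
      "; fs ", x$fs, " Hz, ", x$epoch_seconds, " s epochs\n", sep = "")
  cat("  informative pairs: ", nrow(x$informative),
      "; noise_sd ", x$noise_sd, ", day_sd ", x$day_sd,
      if (!is.null(x$day_effect)) " (fixed day effects)", "\n", sep = "")
  invisible(x)
}

#' Feature names of a synthetic model
#' @param model a `synthetic_model`.
#' @return character vector of feature column names in channel-major order.
#' @export
model_feature_names <- function(model) {
  feature_names(model$channel_names, model$bands)
}

#' Informative feature names of a synthetic model
#' @param model a `synthetic_model`.
#' @return feature column names of the (channel, band) pairs carrying a
#'   class effect.
#' @export
informative_features <- function(model) {
  with(model$informative,
       paste(model$channel_names[channel], model$bands$name[band], sep = "_"))
}
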