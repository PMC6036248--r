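## Named synthetic worlds. The drift magnitudes are free parameters of
## the generator (no distributional description of real inter-day drift
## exists to estimate them from); they are fixed here once, with the
## reasoning in the methods vignette, and shared by the documentation
## examples and the acceptance test bed alike.

#' Preset synthetic worlds
#'
#' Convenience constructors for the scenario families the protocol and
#' selection machinery is validated against. All presets share the
#' 5-day, 3-class design; `...` is passed through to
#' [synthetic_model()] (e.g. to change `n_channels`,
#' `epochs_per_day_per_class` or `seed`).
#'
#' * `preset_chance()` — class effect zero: every protocol must sit at
#'   the 1/3 chance level.
#' * `preset_separable()` — strong class effect on *every* feature, no
#'   day drift, low noise: every protocol must saturate. (Making all
#'   features informative matters: z-scoring amplifies pure-noise
#'   features to unit variance, so even a tiny fraction of noise
#'   features keeps an isotropic kernel off the accuracy ceiling.)
#' * `preset_strong_drift()` — strong class effect with day drift of
#'   comparable magnitude: within-day stays high while cross-day
#'   collapses.
#' * `preset_moderate_drift()` — moderate drift: the regime where
#'   pooling more training days pays off gradually.
#' * `preset_within_day_drift()` — adds slow within-day drift so
#'   accuracy degrades as train/test blocks grow farther apart.
#' * `preset_noise_drift()` — strong drift confined to non-informative
#'   features: the regime where discarding nuisance features helps.
#' * `preset_rfe_recovery()` — the feature-recovery bed: 42 features
#'   over 7 channels, 8 informative, drift on all features calibrated
#'   so pooled-days accuracy sits in the 55-70% range (typical of
#'   cross-day emotion decoding) where
#'   accuracy-loss ranking is informative (neither saturated nor
#'   chance).
#'
#' @param ... overrides forwarded to [synthetic_model()].
#' @return a `synthetic_model`.
#' @name presets
NULL

preset_args <- function(defaults, dots) {
  defaults[names(dots)] <- dots
  do.call(synthetic_model, defaults)
}

#' @rdname presets
#' @export
preset_chance <- function(...) {
  preset_args(list(n_channels = 4L, effect_size = 0,
                   noise_sd = 0.2, day_sd = 0.15,
                   epochs_per_day_per_class = c(20L, 24L, 20L, 22L, 24L)),
              list(...))
}

#' @rdname presets
#' @export
preset_separable <- function(...) {
  dots <- list(...)
  nch <- dots$n_channels %||% 4L
  preset_args(list(n_channels = nch, effect_size = 2,
                   noise_sd = 0.02, day_sd = 0,
                   informative = expand.grid(channel = seq_len(nch),
                                             band = 1:6),
                   epochs_per_day_per_class = c(20L, 24L, 20L, 22L, 24L)),
              dots)
}

#' @rdname presets
#' @export
preset_strong_drift <- function(...) {
  preset_args(list(n_channels = 4L, effect_size = 0.6,
                   noise_sd = 0.15, day_sd = 0.6,
                   epochs_per_day_per_class = c(20L, 24L, 20L, 22L, 24L)),
              list(...))
}

#' @rdname presets
#' @export
preset_moderate_drift <- function(...) {
  preset_args(list(n_channels = 4L, effect_size = 0.35,
                   noise_sd = 0.25, day_sd = 0.3,
                   epochs_per_day_per_class = c(20L, 24L, 20L, 22L, 24L)),
              list(...))
}

#' @rdname presets
#' @export
preset_within_day_drift <- function(...) {
  preset_args(list(n_channels = 3L, effect_size = 0.3,
                   noise_sd = 0.25, day_sd = 0,
                   within_day_drift_sd = 2,
                   epochs_per_day_per_class = c(150L, 150L, 150L, 150L, 150L)),
              list(...))
}

#' @rdname presets
#' @export
preset_noise_drift <- function(...) {
  preset_args(list(n_channels = 7L, effect_size = 0.5,
                   noise_sd = 0.2, day_sd = 1.2,
                   day_effect_on = "noninformative",
                   epochs_per_day_per_class = c(24L, 30L, 26L, 24L, 28L)),
              list(...))
}

#' @rdname presets
#' @export
preset_rfe_recovery <- function(...) {
  preset_args(list(n_channels = 7L, effect_size = 0.5,
                   noise_sd = 0.2, day_sd = 1.0,
                   day_effect_on = "all",
                   epochs_per_day_per_class = c(24L, 30L, 26L, 24L, 28L)),
              list(...))
}
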