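## Feature-level generator: draws band powers directly from the
## log-linear model, bypassing signal synthesis. Fast path used by the
## protocol and feature-selection test beds.

#' Generate a multi-day feature-level study for one subject
#'
#' Draws, for every day, class and epoch, the channels x bands log10
#' band-power surface `baseline + class_effect + day_effect (+ drift) +
#' noise` and returns the powers on the linear scale (`10^x`) as a
#' [subject_study()] of per-day [feature_table()]s.
#'
#' Day offsets are drawn `Normal(0, day_sd^2)` fresh for this
#' realization unless the model carries a fixed `day_effect`. Epoch rows
#' within a day are in temporal order (class blocks in the order of
#' `model$classes`, epochs ordered within each block), so the window-width
#' protocol can alternate train/test blocks over them.
#'
#' @param model a [synthetic_model()].
#' @param subject_id subject identifier (integer or string); combined
#'   with the model seed to give each subject an independent stream.
#' @return a `subject_study`.
#' @export
generate_feature_study <- function(model, subject_id = 1L) {
  stopifnot(inherits(model, "synthetic_model"))
  withr::with_seed(derive_seed(model$seed, "feature", subject_id), {
    realization_study(model, subject_id)
  })
}

## Shared with the signal-level path: returns the per-epoch linear-scale
## target powers plus metadata, so both generators draw from the exact
## same log-linear model.
realization_study <- function(model, subject_id) {
  nc <- model$n_channels
  nb <- n_bands(model$bands)
  nd <- model$n_days
  classes <- model$classes

  delta <- model$day_effect
  if (is.null(delta)) {
    delta <- array(stats::rnorm(nd * nc * nb, 0, model$day_sd),
                   dim = c(nd, nc, nb))
  }
  inf_scale <- if (model$day_effect_on == "noninformative") 0 else
    if (!is.null(model$day_sd_informative) && model$day_sd > 0)
      model$day_sd_informative / model$day_sd else 1
  if (inf_scale != 1 && nrow(model$informative)) {
    for (j in seq_len(nrow(model$informative)))
      delta[, model$informative$channel[j], model$informative$band[j]] <-
        delta[, model$informative$channel[j], model$informative$band[j]] *
        inf_scale
  }

  fnames <- model_feature_names(model)
  day_tables <- vector("list", nd)
  for (d in seq_len(nd)) {
    m <- model$epochs_per_day_per_class[d]
    n_rows <- m * length(classes)
    drift <- NULL
    if (model$within_day_drift_sd > 0) {
      drift <- matrix(stats::rnorm(nc * nb, 0, model$within_day_drift_sd),
                      nc, nb)
    }
    # surface per class, channel-major flattening to match fnames
    rows <- matrix(0, n_rows, nc * nb)
    cls <- character(n_rows)
    epo <- integer(n_rows)
    r <- 0L
    for (l in seq_along(classes)) {
      mu <- model$baseline + model$class_effect[l, , ] + delta[d, , ]
      for (e in seq_len(m)) {
        r <- r + 1L
        x <- mu
        if (!is.null(drift)) {
          # each class is a parallel temporal stream over the session,
          # sharing the day's drift profile: drift stays a pure
          # nuisance in time, never a class confound
          pos <- (e - (m + 1) / 2) / m  # in (-0.5, 0.5)
          x <- x + drift * pos
        }
        eps <- matrix(stats::rnorm(nc * nb, 0, model$noise_sd), nc, nb)
        rows[r, ] <- as.vector(t(x + eps))  # channel-major
        cls[r] <- classes[l]
        epo[r] <- e
      }
    }
    colnames(rows) <- fnames
    day_tables[[d]] <- feature_table(10^rows, subject = subject_id,
                                     day = d, class = cls, epoch = epo)
  }
  names(day_tables) <- as.character(seq_len(nd))
  subject_study(day_tables, n_days = nd,
                check_classes = length(classes) >= 3L)
}

#' Generate feature-level studies for several subjects
#'
#' @param model a [synthetic_model()].
#' @param subject_ids vector of subject identifiers.
#' @return named list of `subject_study` objects.
#' @export
generate_cohort <- function(model, subject_ids) {
  out <- lapply(subject_ids, function(s) generate_feature_study(model, s))
  names(out) <- as.character(subject_ids)
  out
}
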