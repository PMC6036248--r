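#' Canonical EEG frequency band scheme
#'
#' Returns the band scheme used throughout the package: an ordered
#' data frame of `(name, f_low, f_high)` rows defining half-open
#' frequency intervals `[f_low, f_high)`. Shared edges (4, 8, 13, 30,
#' 44 Hz) are therefore assigned uniquely to the upper band.
#'
#' @details The default six bands are delta `[0.5, 4)`, theta `[4, 8)`,
#' alpha `[8, 13)`, beta `[13, 30)`, low gamma `[30, 44)` and high gamma
#' `[44, 100)` Hz. Band power is the integral of spectral density over
#' the interval, so the six bands approximately tile total power in
#' `[0.5, 100)` Hz.
#'
#' @param bands optional data frame with columns `name`, `f_low`,
#'   `f_high` to validate and use instead of the default.
#' @return a `band_scheme` data frame with columns `name`, `f_low`, `f_high`.
#' @examples
#' default_bands()
#' @export
default_bands <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      name  = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
      f_low = c(0.5, 4, 8, 13, 30, 44),
      f_high = c(4, 8, 13, 30, 44, 100),
      stringsAsFactors = FALSE
    )
  }
  validate_bands(bands)
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "f_low", "f_high") %in% names(bands)))
  if (any(bands$f_high <= bands$f_low))
    stop("band edges must be strictly increasing within each band")
  if (is.unsorted(bands$f_low))
    stop("bands must be ordered by increasing f_low")
  if (anyDuplicated(bands$name))
    stop("band names must be unique")
  class(bands) <- c("band_scheme", "data.frame")
  bands
}

n_bands <- function(bands) nrow(bands)

## Channel-major feature column names: all bands of channel 1, then
## channel 2, ... Stable ordering convention across the package.
feature_names <- function(channel_names, bands) {
  as.vector(t(outer(channel_names, bands$name, paste, sep = "_")))
}

#' Parse feature column names into channel and band
#'
#' Inverts the `"<channel>_<band>"` naming convention used for feature
#' columns (e.g. `"CH3_low_gamma"`).
#'
#' @param features character vector of feature column names.
#' @param bands a band scheme (band names are needed to split the name
#'   unambiguously, since band names may contain underscores).
#' @return data frame with columns `feature`, `channel`, `band`.
#' @export
parse_feature_names <- function(features, bands = default_bands()) {
  band_alt <- paste(bands$name, collapse = "|")
  rx <- paste0("^(.*)_(", band_alt, ")$")
  ok <- grepl(rx, features)
  if (!all(ok))
    stop("unparseable feature names: ", paste(features[!ok], collapse = ", "))
  data.frame(
    feature = features,
    channel = sub(rx, "\\1", features),
    band = sub(rx, "\\2", features),
    stringsAsFactors = FALSE
  )
}
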