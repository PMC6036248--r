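## Confusion matrices, paired condition comparisons and run provenance.

#' Confusion matrix with the predicted-row / true-column convention
#'
#' Accumulates counts into (predicted label row, true label column)
#' cells and row-normalizes, so each row shows how predictions of that
#' label distribute over the true labels.
#'
#' @param true,predicted equal-length label vectors.
#' @param classes ordered label set (default positive, neutral,
#'   negative); any label outside it is an error.
#' @return a `confusion_matrix`: list with `counts` and `proportions`
#'   (row-normalized; an all-zero row stays zero).
#' @export
confusion_matrix <- function(true, predicted,
                             classes = c("positive", "neutral", "negative")) {
  if (length(true) != length(predicted))
    stop("label vectors must have equal length")
  unknown <- setdiff(unique(c(true, predicted)), classes)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  counts <- table(factor(predicted, levels = classes),
                  factor(true, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(predicted = classes, true = classes))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, proportions = props, classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat("<confusion_matrix> rows = predicted, columns = true\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' Paired comparison of per-subject accuracies
#'
#' Paired t statistic on the per-subject differences `a - b`.
#' Conventions for the degenerate cases: identical vectors give
#' `t = 0, p = 1`; a nonzero constant difference (zero variance) is
#' reported as an infinite statistic with `p = 0` and flagged
#' `degenerate = TRUE`.
#'
#' @param a,b equal-length (`>= 2`) numeric vectors, paired by subject.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   referring to `mean(a - b)`.
#' @return list with `statistic`, `p.value`, `df`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_comparison <- function(a, b, alternative = "two.sided") {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need >= 2 pairs")
  d <- a - b
  if (all(d == 0))
    return(list(statistic = 0, p.value = 1, df = length(d) - 1,
                mean_diff = 0, degenerate = FALSE))
  if (stats::sd(d) == 0) {
    sgn <- sign(mean(d))
    p <- switch(alternative,
                two.sided = 0,
                greater = if (sgn > 0) 0 else 1,
                less = if (sgn < 0) 0 else 1)
    return(list(statistic = sgn * Inf, p.value = p, df = length(d) - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d), degenerate = FALSE)
}

## ---- run configuration & provenance ------------------------------------

#' Assemble a run configuration
#'
#' Bundles everything a run depends on — master seed, band scheme,
#' classifier config, protocol defaults and synthetic-model parameters
#' — into one object that round-trips losslessly through JSON, plus a
#' content hash embedded in every results file.
#'
#' @param seed master seed.
#' @param bands band scheme.
#' @param classifier a [classifier_config()].
#' @param repetitions_wdc,repetitions_lndi protocol repetition defaults.
#' @param M,vote_threshold,step feature-selection defaults.
#' @param model optional [synthetic_model()] parameters to record.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, bands = default_bands(),
                       classifier = classifier_config(),
                       repetitions_wdc = 5L, repetitions_lndi = 10L,
                       M = 100L, vote_threshold = 3L, step = 1L,
                       model = NULL) {
  structure(list(
    seed = as.integer(seed),
    bands = as.data.frame(bands),
    classifier = unclass(classifier),
    repetitions_wdc = as.integer(repetitions_wdc),
    repetitions_lndi = as.integer(repetitions_lndi),
    M = as.integer(M), vote_threshold = as.integer(vote_threshold),
    step = as.integer(step),
    model = if (!is.null(model)) model_parameters(model)
  ), class = "run_config")
}

model_parameters <- function(model) {
  list(n_channels = model$n_channels, n_days = model$n_days,
       classes = model$classes, fs = model$fs,
       epoch_seconds = model$epoch_seconds,
       epochs_per_day_per_class = model$epochs_per_day_per_class,
       noise_sd = model$noise_sd, day_sd = model$day_sd,
       day_effect_on = model$day_effect_on,
       within_day_drift_sd = model$within_day_drift_sd,
       seed = model$seed)
}

#' Write / read a run configuration as JSON
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$bands <- validate_bands(as.data.frame(x$bands))
  x$classifier <- do.call(classifier_config, x$classifier[
    c("backend", "cost", "gamma", "standardize", "seed")])
  structure(x, class = "run_config")
}

#' Content hash of a run configuration
#'
#' Polynomial rolling hash (base 131 mod 2^31 - 1) of the canonical
#' JSON serialization; embedded in result files so outputs can be
#' traced to the exact configuration.
#'
#' @param cfg a [run_config()] (or any JSON-serializable object).
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                     digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
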