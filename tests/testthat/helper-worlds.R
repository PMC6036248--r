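# Shared fixture builders. All fixtures are generated in code at test
# time; sizes are kept small so the full suite stays within minutes.

tiny_epc <- c(8L, 10L, 9L, 8L, 12L)   # day totals 24..36, M_min = 24

tiny_separable <- function(seed = 1, ...) {
  preset_separable(seed = seed, epochs_per_day_per_class = tiny_epc, ...)
}

tiny_chance <- function(seed = 1, ...) {
  preset_chance(seed = seed, epochs_per_day_per_class = tiny_epc, ...)
}

# A 40-feature restriction of a 7-channel (42-feature) study, with the
# 8 informative features included and positions shuffled so the
# deterministic index tie-break does not align with informativeness.
restrict_40 <- function(study, model, seed = 1) {
  feats <- study_features(study)
  inf <- informative_features(model)
  keep <- withr::with_seed(derive_seed(seed, "restrict"), {
    sample(c(inf, setdiff(feats, inf)[seq_len(40 - length(inf))]))
  })
  study_select_features(study, keep)
}

# Gaussian (possibly negative) feature tables for classifier-contract
# tests; class centroids supplied per class.
gaussian_table <- function(n_per_class, centroids, sd = 1, seed = 1,
                           day = 1L) {
  classes <- names(centroids)
  p <- length(centroids[[1]])
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(classes, function(cl) {
      matrix(stats::rnorm(n_per_class * p, mean = rep(centroids[[cl]],
                                                      each = n_per_class),
                          sd = sd), n_per_class, p)
    }))
    colnames(rows) <- paste0("F", seq_len(p))
    # shift into a matrix with arbitrary sign; bypass band-power
    # non-negativity by building the data frame directly
    df <- data.frame(row_id = sprintf("g%s_%d", day, seq_len(nrow(rows))),
                     subject = 1L, day = day,
                     class = rep(classes, each = n_per_class),
                     epoch = rep(seq_len(n_per_class), length(classes)),
                     rows, stringsAsFactors = FALSE)
    class(df) <- c("feature_table", "data.frame")
    df
  })
}

cfg_raw <- function(...) classifier_config(transform = "none", ...)

# single-channel epoch with a given signal
tone_epoch <- function(x, fs) epoch_array(matrix(x, 1), fs = fs,
                                          channel_names = "CH1")

sine <- function(freq, fs, seconds, amp = 1, phase = 0) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}
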