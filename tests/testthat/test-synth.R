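test_that("noise-free degenerate model reproduces 10^baseline exactly", {
  m <- synthetic_model(n_channels = 3, effect_size = 0, noise_sd = 0,
                       day_sd = 0, epochs_per_day_per_class = tiny_epc,
                       seed = 7)
  study <- generate_feature_study(m, 1)
  expected <- 10^as.vector(t(m$baseline))   # channel-major
  for (d in names(study)) {
    fm <- feature_matrix(study[[d]])
    expect_equal(unname(fm),
                 matrix(expected, nrow(fm), ncol(fm), byrow = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("same seed regenerates a bit-identical study; subjects differ", {
  m <- synthetic_model(n_channels = 2, epochs_per_day_per_class = tiny_epc,
                       seed = 11)
  s1 <- generate_feature_study(m, 1)
  s2 <- generate_feature_study(m, 1)
  expect_identical(s1, s2)
  s3 <- generate_feature_study(m, 2)
  expect_false(identical(feature_matrix(s1[[1]]), feature_matrix(s3[[1]])))
  # signal path is deterministic too
  e1 <- generate_signal_study(m, 1, days = 1)
  e2 <- generate_signal_study(m, 1, days = 1)
  expect_identical(e1[[1]]$data, e2[[1]]$data)
})

test_that("empirical class effect matches the generative model (MC)", {
  # +0.5 on positive, -0.5 on negative, on 8 informative pairs
  inf <- data.frame(channel = rep(1:4, each = 2), band = rep(5:6, 4))
  gamma <- array(0, dim = c(3, 4, 6))
  for (j in seq_len(nrow(inf)))
    gamma[, inf$channel[j], inf$band[j]] <- c(0.5, 0, -0.5)
  m <- synthetic_model(n_channels = 4, class_effect = gamma,
                       informative = inf, noise_sd = 0.1, day_sd = 0,
                       epochs_per_day_per_class = rep(40L, 5), seed = 3)
  study <- generate_feature_study(m, 1)
  all_rows <- do.call(rbind, lapply(study, as.data.frame))
  inf_feats <- informative_features(m)
  lp <- log10(as.matrix(all_rows[inf_feats]))
  pos <- all_rows$class == "positive"
  neu <- all_rows$class == "neutral"
  expect_equal(sum(pos), 200)                  # 600 epochs over 3 classes
  diff_per_pair <- colMeans(lp[pos, ]) - colMeans(lp[neu, ])
  se <- 0.1 * sqrt(1 / sum(pos) + 1 / sum(neu)) / sqrt(length(inf_feats))
  expect_lt(abs(mean(diff_per_pair) - 0.5), 3 * se)
})

test_that("model validation rejects bad parameters", {
  expect_error(synthetic_model(epochs_per_day_per_class = c(1, 2, 3)),
               "counts")
  expect_error(synthetic_model(fs = 150), "twice the highest band edge")
  expect_error(synthetic_model(noise_sd = -1), "noise_sd")
  expect_error(synthetic_model(noise_sd = NaN), "noise_sd")
  # class effects must balance over classes
  g <- array(0.1, dim = c(3, 60, 6))
  expect_error(synthetic_model(class_effect = g), "zero over classes")
})

test_that("band-limited synthesis confines and scales power", {
  bands <- default_bands()
  # zero targets -> silence
  expect_identical(eegdays:::synth_multiband(rep(0, 6), bands, 500, 2500),
                   rep(0, 2500))
  # alpha-only component: >= 90% of periodogram power in [8, 13)
  withr::with_seed(5, {
    x <- eegdays:::synth_multiband(c(0, 0, 1, 0, 0, 0), bands, 500, 2500)
  })
  spec <- eegdays:::periodogram_psd(x, 500)
  in_band <- spec$freq >= 8 & spec$freq < 13
  expect_gte(sum(spec$psd[in_band]) / sum(spec$psd), 0.9)
  # realized power equals the target exactly (scaled synthesis)
  expect_equal(mean(x^2), 1, tolerance = 1e-10)
  expect_error(eegdays:::band_limited_noise(200, 300, 500, 2500, 1),
               "Nyquist")
})

test_that("Welch band powers of synthesized epochs track targets (MC)", {
  m <- synthetic_model(n_channels = 1, effect_size = 0, noise_sd = 0,
                       day_sd = 0, fs = 250, epoch_seconds = 5,
                       epochs_per_day_per_class = c(34L, rep(1L, 4)),
                       seed = 9)
  epochs <- generate_signal_study(m, 1, days = 1)
  expect_length(epochs, 102)
  target <- 10^m$baseline[1, ]
  # direct-DFT oracle: synthesis is exact per band by construction
  dp <- t(sapply(epochs, function(e)
    eegdays:::integrate_bands(eegdays:::periodogram_psd(e$data[1, ], e$fs),
                              default_bands())))
  expect_equal(colMeans(dp) / target, rep(1, 6), tolerance = 1e-6,
               ignore_attr = TRUE)
  # Welch tracks targets within 15% wherever its 2-Hz resolution can
  # represent the band; delta/theta are biased by segment detrending
  # and edge leakage (see vignette / ledger)
  bp <- t(sapply(epochs, function(e) welch_band_powers(e)[1, ]))
  rel <- colMeans(bp) / target
  expect_true(all(abs(rel[3:6] - 1) < 0.15))
  expect_gt(rel[["delta"]], 0.3)   # documented low-frequency bias
  expect_lt(rel[["theta"]], 2.0)
})

test_that("feature- and signal-level paths agree on class ordering", {
  m <- synthetic_model(n_channels = 2, effect_size = 0.8, noise_sd = 0.1,
                       day_sd = 0, fs = 250,
                       informative = data.frame(channel = 1, band = 5),
                       epochs_per_day_per_class = c(34L, rep(1L, 4)),
                       seed = 13)
  fstudy <- generate_feature_study(m, 1)
  sig <- generate_signal_study(m, 1, days = 1)
  ft_sig <- extract_features(sig)
  feat <- informative_features(m)
  rank_of <- function(tab) {
    means <- tapply(tab[[feat]], tab$class, mean)
    names(sort(means))
  }
  expect_identical(rank_of(as.data.frame(ft_sig)),
                   rank_of(as.data.frame(fstudy[["1"]])))
})

test_that("zero day_sd makes days exchangeable (property)", {
  n_sig <- 0L
  trials <- 100L
  for (i in seq_len(trials)) {
    m <- synthetic_model(n_channels = 2, effect_size = 0, day_sd = 0,
                         n_days = 2, noise_sd = 0.2,
                         epochs_per_day_per_class = c(10L, 10L),
                         seed = 1000 + i)
    st <- generate_feature_study(m, 1)
    p <- stats::t.test(log10(st[[1]]$CH1_alpha),
                       log10(st[[2]]$CH1_alpha))$p.value
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 5L)   # non-significant at alpha = .01 in >= 95 %
})

test_that("reference channels carry the common mode and re-referencing removes it", {
  m <- synthetic_model(n_channels = 2, effect_size = 0, noise_sd = 0,
                       day_sd = 0, fs = 250,
                       epochs_per_day_per_class = c(1L, rep(1L, 4)),
                       seed = 21)
  with_ref <- generate_signal_study(m, 1, days = 1,
                                    reference_channels = TRUE)[[1]]
  expect_identical(with_ref$channel_names, c("CH1", "CH2", "M1", "M2"))
  clean <- rereference(with_ref, c("M1", "M2"))
  bare <- generate_signal_study(m, 1, days = 1)[[1]]
  expect_equal(clean$data, bare$data, tolerance = 1e-9)
})
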