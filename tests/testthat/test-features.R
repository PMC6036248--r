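test_that("rereference subtracts the mastoid mean and drops references", {
  a <- c(1, 2, 3, 4)
  b <- c(3, 2, 1, 0)
  sig <- c(10, 20, 30, 40)
  ep <- epoch_array(rbind(sig, a, b), fs = 4,
                    channel_names = c("CZ", "M1", "M2"))
  out <- rereference(ep, c("M1", "M2"))
  expect_identical(out$channel_names, "CZ")
  expect_equal(out$data["CZ", ], sig - (a + b) / 2)

  # zero references leave data channels untouched
  ep0 <- epoch_array(rbind(sig, 0, 0), fs = 4,
                     channel_names = c("CZ", "M1", "M2"))
  expect_equal(rereference(ep0, c("M1", "M2"))$data["CZ", ], sig)

  # a common-mode signal on every channel is removed exactly
  cm <- sin(1:4)
  epc <- epoch_array(rbind(sig + cm, a + cm, b + cm), fs = 4,
                     channel_names = c("CZ", "M1", "M2"))
  expect_equal(rereference(epc, c("M1", "M2"))$data["CZ", ],
               sig - (a + b) / 2)

  expect_error(rereference(ep, "M9"), "unknown reference")
})

test_that("decimate halves 1 kHz to 500 Hz and preserves in-band tones", {
  x <- sine(10, 1000, 5)
  ep <- epoch_array(matrix(x, 1), fs = 1000, channel_names = "CH1")
  out <- decimate(ep, 500)
  expect_equal(out$fs, 500)
  expect_equal(ncol(out$data), 2500)   # 5000 -> 2500 samples
  # 10 Hz sine survives with < 1 % amplitude error
  ref <- sine(10, 500, 5)
  expect_lt(max(abs(out$data[1, ] - ref)), 0.01)

  expect_identical(decimate(ep, 1000), ep)            # identity
  expect_error(decimate(ep, 400), "non-integer")
})

test_that("welch band powers behave on canonical inputs", {
  fs <- 500
  zero <- tone_epoch(rep(0, fs * 5), fs)
  expect_true(all(welch_band_powers(zero) == 0))

  # unit 10 Hz sine: alpha takes >= 90 % of the 6-band total
  ep10 <- tone_epoch(sine(10, fs, 5), fs)
  bp <- welch_band_powers(ep10)[1, ]
  expect_gte(bp[["alpha"]] / sum(bp), 0.9)

  # equal-amplitude tones in two wide bands carry equal band power
  ep2 <- tone_epoch(sine(20, fs, 5) + sine(40, fs, 5), fs)
  bp2 <- welch_band_powers(ep2)[1, ]
  expect_lt(abs(bp2[["beta"]] - bp2[["low_gamma"]]) /
              max(bp2[["beta"]], bp2[["low_gamma"]]), 0.1)

  # a 6 Hz tone sits one 2-Hz bin from the theta/alpha edge: the
  # Hamming +1-bin sidelobe (~13 %) leaks into alpha, so theta captures
  # ~87 % of the tone (see the methods vignette on band-edge resolution)
  ep3 <- tone_epoch(sine(6, fs, 5), fs)
  bp3 <- welch_band_powers(ep3)[1, ]
  expect_gt(bp3[["theta"]] / sum(bp3), 0.80)
  expect_lt(bp3[["theta"]] / sum(bp3), 0.95)

  # band above Nyquist is rejected
  lo_fs <- epoch_array(matrix(rnorm(500), 1), fs = 100)
  expect_error(welch_band_powers(lo_fs), "Nyquist")
})

test_that("a 5-s epoch at 500 Hz yields 19 half-overlapping segments", {
  # 500-ms window, 50 % overlap: starts at 0, 125, ..., 2250
  spec <- eegdays:::welch_psd(rnorm(2500), 500)
  starts <- seq(1, 2500 - 250 + 1, by = 125)
  expect_length(starts, 19)
  expect_equal(spec$df, 2)
})

test_that("six bands approximately tile total band-limited power", {
  withr::with_seed(31, {
    x <- eegdays:::synth_multiband(c(2, 1, 1.5, 1, 0.5, 0.5),
                                   default_bands(), 500, 2500)
  })
  spec <- eegdays:::welch_psd(x, 500)
  band_sum <- sum(eegdays:::integrate_bands(spec, default_bands()))
  total <- sum(spec$psd[spec$freq >= 0.5 & spec$freq < 100]) * spec$df
  expect_lte(band_sum, total * (1 + 1e-9))
  expect_gt(band_sum, total * 0.98)
})

test_that("Welch matches the direct-DFT oracle for interior tones", {
  fs <- 500
  for (f0 in c(10, 20, 36, 70)) {
    ep <- tone_epoch(sine(f0, fs, 5), fs)
    welch <- welch_band_powers(ep)[1, ]
    oracle <- eegdays:::integrate_bands(
      eegdays:::periodogram_psd(ep$data[1, ], fs), default_bands())
    band <- which(default_bands()$f_low <= f0 & default_bands()$f_high > f0)
    expect_lt(abs(welch[band] - oracle[band]) / oracle[band], 0.05,
              label = paste("tone", f0, "Hz band-power deviation"))
  }
})

test_that("extract_features builds the channel-major table", {
  fs <- 200
  make_ep <- function(names, perm = seq_along(names), day = 1L, ep = 1L) {
    data <- outer(seq_along(names), 1:(fs * 5),
                  function(i, t) sin(2 * pi * 10 * t / fs) * i)
    epoch_array(data[perm, , drop = FALSE], fs = fs,
                channel_names = names[perm], subject = "s1", day = day,
                class = "neutral", epoch = ep)
  }
  nm16 <- paste0("CH", 1:16)
  ft <- extract_features(list(make_ep(nm16), make_ep(nm16, ep = 2L)),
                         bands = default_bands()[1:6, ])
  expect_length(feature_cols(ft), 96)    # 16 channels x 6 bands
  expect_equal(ft$class, c("neutral", "neutral"))

  # permuted channel order gives the identical table after alignment
  ft_perm <- extract_features(list(make_ep(nm16),
                                   make_ep(nm16, perm = 16:1, ep = 2L)))
  expect_equal(feature_matrix(ft_perm)[2, feature_cols(ft)],
               feature_matrix(ft)[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  # inconsistent channel sets are rejected
  expect_error(extract_features(list(make_ep(nm16),
                                     make_ep(paste0("X", 1:16)))),
               "inconsistent channel names")
})
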