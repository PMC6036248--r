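test_that("selection/validation split is stratified, disjoint, exhaustive", {
  m <- synthetic_model(n_channels = 2, epochs_per_day_per_class = rep(20L, 5),
                       seed = 2)
  st <- generate_feature_study(m, 1)
  halves <- split_selection_validation(st, seed = 9)
  for (d in names(st)) {
    sel <- halves$selection[[d]]; val <- halves$validation[[d]]
    expect_equal(nrow(sel), 30)          # 60 -> 30/30 per day
    expect_length(intersect(sel$row_id, val$row_id), 0)
    expect_setequal(c(sel$row_id, val$row_id), st[[d]]$row_id)
    expect_true(all(table(sel$class) == 10))
  }
  expect_equal(split_selection_validation(st, seed = 9), halves)
  expect_false(identical(split_selection_validation(st, seed = 10), halves))
})

test_that("loo ranking counts fits and breaks ties by lowest index", {
  train <- gaussian_table(10, list(positive = c(5, 0, 0),
                                   neutral = c(0, 5, 0),
                                   negative = c(0, 0, 5)), seed = 1)
  rk <- rank_features_loo(train, train, cfg_raw())
  expect_equal(rk$n_fits, 5)             # P = 3: 3 + 2 fits
  expect_length(rk$elimination_order, 3)
  expect_setequal(rk$elimination_order, c("F1", "F2", "F3"))

  # identical features everywhere: pure tie-break, index order
  const <- train
  const[c("F1", "F2", "F3")] <- 1
  rk2 <- rank_features_loo(const, const, cfg_raw())
  expect_identical(rk2$elimination_order, c("F1", "F2", "F3"))
})

test_that("a single informative feature survives to the end", {
  wins <- 0L
  for (s in 1:10) {
    cent <- list(positive = c(4, rep(0, 9)), neutral = c(0, rep(0, 9)),
                 negative = c(-4, rep(0, 9)))
    train <- gaussian_table(12, cent, sd = 1, seed = 100 + s)
    test <- gaussian_table(12, cent, sd = 1, seed = 200 + s)
    rk <- rank_features_loo(train, test, cfg_raw())
    if (utils::tail(rk$elimination_order, 1) == "F1") wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("step mode eliminates k per round; ranking consistency holds", {
  m <- tiny_separable(seed = 3, n_channels = 2)
  st <- generate_feature_study(m, 1)
  tr <- st[["1"]]; te <- st[["2"]]
  rk1 <- rank_features_loo(tr, te)
  rk3 <- rank_features_loo(tr, te, step = 3)
  expect_setequal(rk3$elimination_order, rk1$elimination_order)
  expect_lt(rk3$n_fits, rk1$n_fits)
  # restricting to the top-M survivors and re-running preserves order
  top <- top_features(rk1, 5)
  rk_top <- rank_features_loo(select_features(tr, top),
                              select_features(te, top))
  expect_identical(rk_top$elimination_order,
                   rk1$elimination_order[match(top, rk1$elimination_order)])
  expect_error(top_features(rk1, 99), "exceeds")
})

test_that("single-pass mode ranks from one leave-one-out round", {
  cent <- list(positive = c(4, 0, 0, 0), neutral = c(0, 4, 0, 0),
               negative = c(-4, -4, 0, 0))
  train <- gaussian_table(12, cent, sd = 1, seed = 31)
  test <- gaussian_table(12, cent, sd = 1, seed = 32)
  rk <- rank_features_loo(train, test, cfg_raw(), recursive = FALSE)
  expect_equal(rk$n_fits, 4)              # one fit per feature
  expect_setequal(rk$elimination_order, paste0("F", 1:4))
  # informative features are ranked above the noise pair
  expect_true(all(utils::tail(rk$elimination_order, 2) %in% c("F1", "F2")))
})

test_that("consensus voting implements the >= 3-of-5 rule", {
  feats <- LETTERS[1:10]
  lists <- list(c("A", "B", "C"), c("A", "B", "D"), c("A", "C", "E"),
                c("A", "B", "F"), c("A", "C", "G"))
  votes <- eegdays:::vote_features(lists, feats)
  expect_equal(unname(votes[c("A", "B", "C")]), c(5L, 3L, 3L))
  expect_setequal(names(votes)[votes >= 3], c("A", "B", "C"))

  same <- replicate(5, c("A", "B", "C"), simplify = FALSE)
  v2 <- eegdays:::vote_features(same, feats)
  expect_setequal(names(v2)[v2 >= 3], c("A", "B", "C"))

  disjoint <- list(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"),
                   c("I", "J"))
  v3 <- eegdays:::vote_features(disjoint, feats)
  expect_length(names(v3)[v3 >= 3], 0)

  expect_error(eegdays:::vote_features(list(c("A", "ZZ")), feats),
               "unknown features")
})

test_that("run_l4di_selection wires folds, votes and budget together", {
  m <- preset_separable(seed = 5, n_channels = 2,
                        epochs_per_day_per_class = rep(16L, 5))
  st <- generate_feature_study(m, 1)
  halves <- split_selection_validation(st, seed = 5)
  sal <- run_l4di_selection(halves$selection, M = 4, seed = 5)
  expect_length(sal$fold_lists, 5)
  expect_true(all(lengths(sal$fold_lists) == 4))
  expect_true(all(sal$votes >= 0 & sal$votes <= 5))
  expect_true(all(sal$votes[sal$selected] >= 3))
  expect_lte(length(sal$selected), floor(5 * 4 / 3))
  expect_error(run_l4di_selection(halves$selection, M = 99), "exceeds")
})

test_that("validate_subset pairs runs and guards against misuse", {
  m <- preset_separable(seed = 7, n_channels = 2,
                        epochs_per_day_per_class = rep(16L, 5))
  st <- generate_feature_study(m, 1)
  halves <- split_selection_validation(st, seed = 7)
  feats <- study_features(st)
  v <- validate_subset(halves$validation, feats, conditions = c(1, 4),
                       repetitions = 2, seed = 7)
  # subset = all features: both columns identical
  expect_equal(v$comparison$acc_all, v$comparison$acc_subset)
  expect_error(validate_subset(halves$validation, character(0)),
               "non-empty")
  expect_error(validate_subset(halves$validation, "NOPE"), "absent")
})

test_that("a pure-noise subset scores at chance", {
  m <- synthetic_model(n_channels = 4, effect_size = 1.5, noise_sd = 0.05,
                       day_sd = 0, epochs_per_day_per_class = rep(16L, 5),
                       seed = 11)
  st <- generate_feature_study(m, 1)
  noise_feats <- setdiff(study_features(st), informative_features(m))[1:6]
  v <- validate_subset(st, noise_feats, conditions = 4,
                       repetitions = 3, seed = 11)
  n_preds <- 3 * 5 * compute_sample_budget(study_day_counts(st))$M_min
  expect_lt(abs(v$comparison$acc_subset - 1 / 3),
            3 * sqrt((1 / 3) * (2 / 3) / n_preds) + 0.02)
})

test_that("leakage audit proves ranking/validation disjointness", {
  m <- preset_separable(seed = 13, n_channels = 2,
                        epochs_per_day_per_class = rep(16L, 5))
  st <- generate_feature_study(m, 1)
  halves <- split_selection_validation(st, seed = 13)
  sal <- run_l4di_selection(halves$selection, M = 4, seed = 13)
  v <- validate_subset(halves$validation, sal, conditions = c(1, 4),
                       repetitions = 2, seed = 13)
  aud <- leakage_audit(sal, v)
  expect_true(aud$disjoint)
  expect_length(aud$overlap, 0)
  # a deliberately contaminated validation set is caught
  bad <- leakage_audit(sal, list(row_ids = sal$row_ids[1]))
  expect_false(bad$disjoint)
})

test_that("contribution rates aggregate selections across subjects", {
  ch <- paste0("CH", 1:3)
  b <- default_bands()
  s1 <- c("CH1_alpha", "CH2_high_gamma")
  s2 <- c("CH1_alpha", "CH3_delta")
  cr <- contribution_rates(list(s1, s2), ch, b)
  expect_equal(cr["CH1", "alpha"], 1)
  expect_equal(cr["CH2", "high_gamma"], 0.5)
  expect_equal(cr["CH3", "delta"], 0.5)
  expect_equal(sum(cr), 2)
  # single subject: 0/1 indicator
  cr1 <- contribution_rates(list(s1), ch, b)
  expect_true(all(cr1 %in% c(0, 1)))
  expect_error(contribution_rates(list("CH9_alpha"), ch, b), "mismatched")
})

test_that("simulated cohort concentrates contribution on informative pairs", {
  mk <- function(s) synthetic_model(n_channels = 4, effect_size = 1,
                                    epochs_per_day_per_class = rep(16L, 5),
                                    seed = s)
  sel <- lapply(1:6, function(s) informative_features(mk(s)))
  m0 <- mk(1)
  cr <- contribution_rates(sel, m0$channel_names, m0$bands)
  inf <- eegdays:::parse_feature_names(informative_features(m0))
  on_inf <- mapply(function(c_, b_) cr[c_, b_], inf$channel, inf$band)
  expect_equal(mean(on_inf), 1)
  expect_equal(sum(cr) - sum(on_inf), 0)   # nothing off the informative set
})
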