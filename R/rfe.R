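## Modified recursive feature elimination: rank features per day-fold
## by the accuracy loss their individual removal causes, recurse to
## exhaustion, take the top-M list per fold, and vote across the 5
## folds; features selected by >= 3 folds form the salient subset,
## which is validated on held-back rows under L1DI..L4DI.

#' Split a study into selection and validation halves
#'
#' Per-day, class-stratified random split: `fraction` of each
#' day/class cell goes to the selection half (used for ranking and
#' voting) and the remainder to the validation half, which ranking
#' never touches. The halves are disjoint by row id and their union is
#' the input.
#'
#' @param study a [subject_study()].
#' @param fraction selection-half fraction (default 0.5).
#' @param seed integer seed; the same seed reproduces the same split.
#' @return list with elements `selection` and `validation`, both
#'   `subject_study` objects.
#' @export
split_selection_validation <- function(study, fraction = 0.5, seed = 1L) {
  sel <- list(); val <- list()
  for (d in names(study)) {
    tab <- study[[d]]
    idx <- withr::with_seed(derive_seed(seed, "split", d), {
      unlist(lapply(sort(unique(tab$class)), function(cl) {
        rows <- which(tab$class == cl)
        n_sel <- floor(fraction * length(rows))
        if (n_sel < 1L || n_sel >= length(rows))
          stop("day ", d, " class '", cl, "' too small to split")
        sample(rows, n_sel)
      }))
    })
    idx <- sort(idx)
    sel[[d]] <- subset_rows(tab, idx)
    val[[d]] <- subset_rows(tab, setdiff(seq_len(nrow(tab)), idx))
  }
  list(selection = structure(sel, class = "subject_study"),
       validation = structure(val, class = "subject_study"))
}

#' Rank features by leave-one-feature-out accuracy loss
#'
#' One elimination round trains, for each of the `F` surviving
#' features, a classifier on the remaining `F - 1` features and scores
#' it on the test table; the feature whose removal leaves the highest
#' accuracy (minimum loss) contributes least and is eliminated. Rounds
#' recurse until one feature remains. Ties on the maximum accuracy are
#' broken toward the lowest feature index (deterministic and
#' seed-independent). With `step = k > 1` the `k` least-contributing
#' features are eliminated per round (tractability mode).
#'
#' @param train,test [feature_table()]s with identical feature columns.
#' @param cfg a [classifier_config()].
#' @param step features eliminated per round (default 1).
#' @param stop_at stop when this many features remain (default 1; a
#'   value `>= 2` is a floor mode that leaves the survivors unordered
#'   at the head of the ranking).
#' @param recursive recurse after each elimination (default TRUE, the
#'   full procedure); `FALSE` derives the whole ranking from the
#'   single initial round of leave-one-feature-out accuracies (a much
#'   cheaper approximation that ignores feature interactions).
#' @return an `rfe_ranking`: `elimination_order` (position 1 = first
#'   eliminated = least contribution; remaining survivors, if
#'   `stop_at > 1`, are appended in index order), `trace` (best
#'   accuracy per round), `n_fits`.
#' @export
rank_features_loo <- function(train, test, cfg = classifier_config(),
                              step = 1L, stop_at = 1L, recursive = TRUE) {
  features <- feature_cols(train)
  if (length(features) < 2L) stop("need >= 2 features to rank")
  if (!setequal(features, feature_cols(test)))
    stop("train and test feature columns differ")
  X <- feature_matrix(train); y <- train$class
  Xte <- as.matrix(test[features]); yte <- test$class
  if (!recursive) {
    accs <- vapply(seq_along(features), function(j) {
      res <- fit_predict_xy(X, y, Xte, cfg, cols = -j)
      mean(res$predicted == yte)
    }, 0)
    if (any(!is.finite(accs))) stop("non-finite accuracy during ranking")
    ord <- order(-accs, seq_along(features))
    return(structure(list(
      elimination_order = features[ord], survivors = character(0),
      trace = max(accs), n_fits = length(features), features = features
    ), class = "rfe_ranking"))
  }
  current <- seq_along(features)
  eliminated <- integer(0)
  trace <- numeric(0)
  n_fits <- 0L
  while (length(current) > max(1L, stop_at)) {
    accs <- vapply(seq_along(current), function(j) {
      res <- fit_predict_xy(X, y, Xte, cfg, cols = current[-j])
      mean(res$predicted == yte)
    }, 0)
    n_fits <- n_fits + length(current)
    if (any(!is.finite(accs))) stop("non-finite accuracy during ranking")
    k <- min(step, length(current) - max(1L, stop_at))
    # highest remaining accuracy = least contribution; ties -> lowest index
    drop_pos <- order(-accs, current)[seq_len(k)]
    eliminated <- c(eliminated, current[sort(drop_pos)])
    trace <- c(trace, max(accs))
    current <- current[-sort(drop_pos)]
  }
  structure(list(
    elimination_order = features[c(eliminated, current)],
    survivors = features[current],
    trace = trace, n_fits = n_fits, features = features
  ), class = "rfe_ranking")
}

#' @export
print.rfe_ranking <- function(x, ...) {
  cat("<rfe_ranking> ", length(x$elimination_order), " features, ",
      x$n_fits, " classifier fits; last eliminated: ",
      paste(utils::tail(x$elimination_order, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Top-M features of a ranking
#'
#' The `M` features eliminated last (or still surviving) — the
#' highest-contribution features.
#'
#' @param ranking an `rfe_ranking`.
#' @param M list size.
#' @return character vector of `M` feature names.
#' @export
top_features <- function(ranking, M) {
  if (M > length(ranking$elimination_order))
    stop("M exceeds the number of ranked features")
  utils::tail(ranking$elimination_order, M)
}

#' Per-fold RFE under L4DI with cross-fold consensus voting
#'
#' Runs the modified RFE once per day-fold of the selection half: each
#' day is held out once; the training set pools `M_min / 4` rows from
#' each of the other 4 days and the test set draws `M_min` rows from
#' the held-out day (budget computed on the selection half). Each
#' fold's top-`M` list casts one vote per feature; features with at
#' least `vote_threshold` (default 3) of 5 votes form the salient
#' subset.
#'
#' @param selection_study the selection half from
#'   [split_selection_validation()].
#' @param cfg a [classifier_config()].
#' @param M top-list size per fold (default 100, the reported choice;
#'   must not exceed the feature count).
#' @param seed master seed for the per-fold row draws.
#' @param step,stop_at passed to [rank_features_loo()].
#' @param vote_threshold votes needed for selection (default 3).
#' @return a `salient_subset`: `votes` (named 0..5 counts over all
#'   features), `selected`, `M`, `fold_lists`, `rankings`, and the row
#'   ids used (for leakage audits).
#' @export
run_l4di_selection <- function(selection_study, cfg = classifier_config(),
                               M = 100L, seed = 1L, step = 1L,
                               stop_at = 1L, vote_threshold = 3L) {
  features <- study_features(selection_study)
  if (M > length(features)) stop("M exceeds the feature count")
  budget <- compute_sample_budget(study_day_counts(selection_study))
  days <- as.integer(names(selection_study))
  nd <- length(days)
  q_train <- budget$M_min %/% (nd - 1L)
  q_test <- budget$M_min
  rankings <- vector("list", nd)
  fold_lists <- vector("list", nd)
  row_ids <- character(0)
  for (f in seq_along(days)) {
    held_out <- days[f]
    sets <- withr::with_seed(derive_seed(seed, "rfe", held_out), {
      tr <- rbind_feature_tables(lapply(setdiff(days, held_out), function(d) {
        tab <- selection_study[[as.character(d)]]
        subset_rows(tab, stratified_sample_idx(tab, q_train))
      }))
      te_tab <- selection_study[[as.character(held_out)]]
      te <- subset_rows(te_tab, stratified_sample_idx(te_tab, q_test))
      list(tr = tr, te = te)
    })
    rk <- rank_features_loo(sets$tr, sets$te, cfg, step = step,
                            stop_at = stop_at)
    rk$fold <- held_out
    rankings[[f]] <- rk
    fold_lists[[f]] <- top_features(rk, M)
    row_ids <- union(row_ids, c(sets$tr$row_id, sets$te$row_id))
  }
  names(rankings) <- names(fold_lists) <- as.character(days)
  votes <- vote_features(fold_lists, features)
  structure(list(
    votes = votes,
    selected = names(votes)[votes >= vote_threshold],
    M = as.integer(M), vote_threshold = as.integer(vote_threshold),
    fold_lists = fold_lists, rankings = rankings,
    budget = budget, seed = seed, row_ids = row_ids
  ), class = "salient_subset")
}

## Count, for every feature, how many fold lists contain it.
vote_features <- function(fold_lists, features) {
  votes <- stats::setNames(integer(length(features)), features)
  for (fl in fold_lists) {
    unknown <- setdiff(fl, features)
    if (length(unknown))
      stop("fold list contains unknown features: ",
           paste(unknown, collapse = ", "))
    votes[fl] <- votes[fl] + 1L
  }
  votes
}

#' @export
print.salient_subset <- function(x, ...) {
  cat("<salient_subset> ", length(x$selected), " features selected (>= ",
      x$vote_threshold, " of ", length(x$fold_lists),
      " votes, M = ", x$M, ")\n", sep = "")
  invisible(x)
}

#' Validate a feature subset under L1DI..L4DI
#'
#' Runs [lndi_evaluate()] on the validation half twice per condition
#' `N` — once with all features and once restricted to `subset` — with
#' identical seeds, so the row draws are paired and the accuracy
#' difference isolates the feature restriction.
#'
#' @param validation_study the validation half from
#'   [split_selection_validation()].
#' @param subset non-empty character vector of feature columns (e.g.
#'   `salient$selected`).
#' @param cfg a [classifier_config()].
#' @param conditions the N values to evaluate (default 1:4).
#' @param repetitions LNDI repetitions (default 10).
#' @param seed master seed.
#' @return a `subset_validation`: `comparison` data frame
#'   (`N`, `acc_all`, `acc_subset`), the underlying `lndi_result`s,
#'   and the row ids used.
#' @export
validate_subset <- function(validation_study, subset,
                            cfg = classifier_config(),
                            conditions = 1:4, repetitions = 10L,
                            seed = 1L) {
  if (is.list(subset) && !is.null(subset$selected)) subset <- subset$selected
  if (length(subset) == 0L) stop("subset must be non-empty")
  missing <- setdiff(subset, study_features(validation_study))
  if (length(missing))
    stop("subset features absent from the study: ",
         paste(missing, collapse = ", "))
  runs_all <- list(); runs_sub <- list()
  comparison <- data.frame(N = as.integer(conditions),
                           acc_all = NA_real_, acc_subset = NA_real_)
  for (i in seq_along(conditions)) {
    N <- conditions[i]
    s <- derive_seed(seed, "validate", N)
    runs_all[[i]] <- lndi_evaluate(validation_study, N, cfg,
                                   repetitions = repetitions, seed = s)
    runs_sub[[i]] <- lndi_evaluate(validation_study, N, cfg,
                                   repetitions = repetitions, seed = s,
                                   features = subset)
    comparison$acc_all[i] <- runs_all[[i]]$acc_lndi
    comparison$acc_subset[i] <- runs_sub[[i]]$acc_lndi
  }
  row_ids <- unique(unlist(c(lapply(runs_all, `[[`, "row_ids"),
                             lapply(runs_sub, `[[`, "row_ids"))))
  structure(list(comparison = comparison, all_features = runs_all,
                 subset_runs = runs_sub, subset = subset,
                 row_ids = row_ids),
            class = "subset_validation")
}

#' Audit selection/validation row disjointness
#'
#' Proves (by row id) that no row used anywhere in ranking/voting was
#' also used in validation — the guard against the feature-selection
#' leakage the half-split exists to prevent.
#'
#' @param selection a `salient_subset` (or anything with a `row_ids`
#'   field) from the selection half.
#' @param validation a `subset_validation` (or anything with a
#'   `row_ids` field) from the validation half.
#' @return list with `disjoint` (logical) and `overlap` (offending ids).
#' @export
leakage_audit <- function(selection, validation) {
  a <- selection$row_ids %||% selection
  b <- validation$row_ids %||% validation
  overlap <- intersect(a, b)
  list(disjoint = length(overlap) == 0L, overlap = overlap,
       n_selection = length(a), n_validation = length(b))
}

#' Contribution rates across subjects
#'
#' `CR(channel, band)` is the fraction of subjects whose salient subset
#' contains that feature — the group-level map of where the selected
#' features live.
#'
#' @param subsets list with one element per subject: a
#'   `salient_subset` or a character vector of selected feature names.
#' @param channel_names ordered channel labels of the shared feature
#'   space (keyed to the actual channel count).
#' @param bands a band scheme.
#' @return a channels x bands matrix with entries in `[0, 1]`.
#' @export
contribution_rates <- function(subsets, channel_names,
                               bands = default_bands()) {
  full_space <- feature_names(channel_names, bands)
  cr <- matrix(0, length(channel_names), n_bands(bands),
               dimnames = list(channel_names, bands$name))
  for (s in subsets) {
    sel <- if (is.list(s)) {
      if (!setequal(names(s$votes), full_space))
        stop("mismatched feature spaces across subjects")
      s$selected
    } else {
      if (length(setdiff(s, full_space)))
        stop("mismatched feature spaces across subjects")
      s
    }
    parsed <- parse_feature_names(sel, bands)
    for (j in seq_len(nrow(parsed)))
      cr[parsed$channel[j], parsed$band[j]] <-
        cr[parsed$channel[j], parsed$band[j]] + 1
  }
  cr / length(subsets)
}
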