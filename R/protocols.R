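## Calibration / evaluation protocols over one subject's 5-day study:
##   WDC  — within-day 80/20, 5 repetitions per day;
##   SCDC — train on one day (80%, count-matched to WDC), test each
##          other day; 5 x 4 grid, 5 repetitions;
##   LNDI — train on N of 5 days under the factor-12 sample budget,
##          test on the held-out 5-N days, all C(5,N) combinations,
##          10 repetitions;
##   window-width — alternate consecutive temporal blocks train/test.

#' Compute the factor-12 sample budget
#'
#' The per-condition sample budget is
#' `M_min = floor(min(M_1..M_5) / 12) * 12`, where `M_i` is day `i`'s
#' row count. Divisibility by 12 makes the per-day training quota
#' `M_min / N` and testing quota `M_min / (5 - N)` integral for every
#' `N` in 1..4.
#'
#' @param day_counts integer vector of per-day sample counts.
#' @return a `sample_budget` list with element `M_min`.
#' @examples
#' compute_sample_budget(c(90, 120, 100, 110, 130))  # 84
#' @export
compute_sample_budget <- function(day_counts) {
  if (length(day_counts) < 2L || any(!is.finite(day_counts)) ||
      any(day_counts <= 0))
    stop("day_counts must be positive counts")
  m <- (min(day_counts) %/% 12L) * 12L
  if (m < 12L)
    stop("insufficient samples: minimum day count below 12 gives a zero budget")
  structure(list(M_min = as.integer(m), day_counts = as.integer(day_counts)),
            class = "sample_budget")
}

## ---- stratified sampling helpers ---------------------------------------

## Draw `n` row indices from a feature table, split as evenly as
## possible over the (sorted) class labels; relies on the current RNG
## state so callers control reproducibility via withr::with_seed.
stratified_sample_idx <- function(ft, n) {
  classes <- sort(unique(ft$class))
  quotas <- split_quota(n, length(classes))
  idx <- integer(0)
  for (i in seq_along(classes)) {
    rows <- which(ft$class == classes[i])
    if (length(rows) < quotas[i])
      stop("too few rows of class '", classes[i], "' (need ", quotas[i],
           ", have ", length(rows), ")")
    idx <- c(idx, sample(rows, quotas[i]))
  }
  sort(idx)
}

## Random stratified train/test split: per class, floor(fraction * n)
## rows to train, the rest to test. Errors when a class would have an
## empty side.
stratified_split_idx <- function(ft, fraction = 0.8) {
  classes <- sort(unique(ft$class))
  train <- integer(0)
  for (cl in classes) {
    rows <- which(ft$class == cl)
    n_tr <- floor(fraction * length(rows))
    if (n_tr < 1L || n_tr >= length(rows))
      stop("too few rows of class '", cl, "' for a stratified ",
           round(fraction * 100), "/", round((1 - fraction) * 100), " split")
    train <- c(train, sample(rows, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(seq_len(nrow(ft)), train)))
}

subset_rows <- function(ft, idx) {
  out <- ft[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ft)
  out
}

#' Training count shared by WDC and SCDC
#'
#' Both protocols train on an 80% draw of a single day; to keep the
#' comparison fair the training sets are capped at the same row count:
#' the smallest 80% pool over the 5 days.
#'
#' @param study a [subject_study()].
#' @param fraction training fraction (default 0.8).
#' @return integer training row count.
#' @export
matched_train_count <- function(study, fraction = 0.8) {
  min(vapply(study, function(d) {
    sum(vapply(split(seq_len(nrow(d)), d$class),
               function(rows) floor(fraction * length(rows)), 0))
  }, 0))
}

protocol_result <- function(protocol, cells, summary, mean_accuracy,
                            repetitions, seed, cfg, extra = list()) {
  structure(c(list(protocol = protocol, cells = cells, summary = summary,
                   mean_accuracy = mean_accuracy,
                   repetitions = repetitions, seed = seed, cfg = cfg),
              extra),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result> ", x$protocol, ": mean accuracy ",
      sprintf("%.4f", x$mean_accuracy), " over ", nrow(x$cells),
      " cells (", x$repetitions, " repetitions, seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

## ---- WDC ----------------------------------------------------------------

#' Within-day classification (WDC)
#'
#' For each day: 5 repetitions of a random class-stratified 80/20 split
#' of that day's rows; the classifier is trained on the 80% (optionally
#' capped at the WDC/SCDC matched count) and scored on the 20%. The
#' per-day accuracy is the mean of the 5 repetitions.
#'
#' @param study a [subject_study()].
#' @param cfg a [classifier_config()].
#' @param repetitions number of random splits per day (default 5).
#' @param seed master seed; each (day, repetition) cell derives its own
#'   child seed so any cell is reproducible in isolation.
#' @param match_train_count cap training draws at
#'   [matched_train_count()] so WDC and SCDC train on equally many rows
#'   (default TRUE).
#' @return a `protocol_result` with one cell per (day, repetition).
#' @export
wdc_evaluate <- function(study, cfg = classifier_config(),
                         repetitions = 5L, seed = 1L,
                         match_train_count = TRUE) {
  cap <- if (match_train_count) matched_train_count(study) else Inf
  cells <- expand.grid(day = as.integer(names(study)),
                       repetition = seq_len(repetitions))
  cells$accuracy <- NA_real_
  cells$n_train <- cells$n_test <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    d <- as.character(cells$day[i]); r <- cells$repetition[i]
    res <- withr::with_seed(
      derive_seed(seed, "wdc", cells$day[i], r), {
        sp <- stratified_split_idx(study[[d]], 0.8)
        tr_idx <- sp$train
        if (length(tr_idx) > cap) {
          tr <- subset_rows(study[[d]], tr_idx)
          tr_idx <- tr_idx[stratified_sample_idx(tr, cap)]
        }
        c(fit_predict(subset_rows(study[[d]], tr_idx),
                      subset_rows(study[[d]], sp$test), cfg)$accuracy,
          length(tr_idx), length(sp$test))
      })
    cells$accuracy[i] <- res[1]
    cells$n_train[i] <- res[2]; cells$n_test[i] <- res[3]
  }
  per_day <- stats::aggregate(accuracy ~ day, cells, mean)
  protocol_result("WDC", cells, per_day, mean(per_day$accuracy),
                  repetitions, seed, cfg,
                  extra = list(train_count_cap = cap))
}

## ---- SCDC ---------------------------------------------------------------

#' Standard cross-day classification (SCDC)
#'
#' For each training day: a random class-stratified 80% draw of that
#' day (capped at the WDC/SCDC matched count) trains the classifier,
#' which is then tested separately on all rows of each of the other 4
#' days, yielding a 5 x 4 accuracy grid; repeated and averaged per cell.
#'
#' @inheritParams wdc_evaluate
#' @return a `protocol_result`; `summary` holds the per-(train day,
#'   test day) grid means.
#' @export
scdc_evaluate <- function(study, cfg = classifier_config(),
                          repetitions = 5L, seed = 1L,
                          match_train_count = TRUE) {
  cap <- if (match_train_count) matched_train_count(study) else Inf
  days <- as.integer(names(study))
  cells <- expand.grid(train_day = days, test_day = days,
                       repetition = seq_len(repetitions))
  cells <- cells[cells$train_day != cells$test_day, ]
  rownames(cells) <- NULL
  cells$accuracy <- NA_real_
  cells$n_train <- cells$n_test <- NA_integer_
  for (ti in days) {
    for (r in seq_len(repetitions)) {
      res <- withr::with_seed(derive_seed(seed, "scdc", ti, r), {
        dtab <- study[[as.character(ti)]]
        sp <- stratified_split_idx(dtab, 0.8)
        tr_idx <- sp$train
        if (length(tr_idx) > cap) {
          tr <- subset_rows(dtab, tr_idx)
          tr_idx <- tr_idx[stratified_sample_idx(tr, cap)]
        }
        train <- subset_rows(dtab, tr_idx)
        vapply(setdiff(days, ti), function(te) {
          c(fit_predict(train, study[[as.character(te)]], cfg)$accuracy,
            nrow(train), nrow(study[[as.character(te)]]))
        }, numeric(3))
      })
      sel <- which(cells$train_day == ti & cells$repetition == r)
      ord <- match(setdiff(days, ti), cells$test_day[sel])
      cells$accuracy[sel][ord] <- res[1, ]
      cells$n_train[sel][ord] <- res[2, ]
      cells$n_test[sel][ord] <- res[3, ]
    }
  }
  grid <- stats::aggregate(accuracy ~ train_day + test_day, cells, mean)
  protocol_result("SCDC", cells, grid, mean(grid$accuracy),
                  repetitions, seed, cfg,
                  extra = list(train_count_cap = cap))
}

## ---- LNDI ---------------------------------------------------------------

#' Learning-N-days-information (LNDI) evaluation
#'
#' For each repetition and each of the `C(5, N)` day combinations, the
#' training set pools `M_min / N` class-stratified rows from each of
#' the `N` training days and the testing set pools `M_min / (5 - N)`
#' rows from each held-out day (`M_min` from
#' [compute_sample_budget()]); the combination accuracy is averaged
#' over combinations, and the final accuracy over the repetitions.
#'
#' @param study a [subject_study()].
#' @param n_train_days N, the number of training days (1..4 for a
#'   5-day study).
#' @param cfg a [classifier_config()].
#' @param repetitions number of re-randomizations (default 10).
#' @param seed master seed; every (repetition, combination) cell
#'   derives its own child seed.
#' @param budget optional [compute_sample_budget()] override.
#' @param features optional feature-column subset; row draws are made
#'   before the restriction, so runs with identical seeds are paired
#'   across feature sets.
#' @return an `lndi_result` (also a `protocol_result`) with fields
#'   `N`, `cells`, per-repetition means and `acc_lndi`, plus the row
#'   ids used (for leakage audits).
#' @export
lndi_evaluate <- function(study, n_train_days, cfg = classifier_config(),
                          repetitions = 10L, seed = 1L, budget = NULL,
                          features = NULL) {
  nd <- length(study)
  N <- as.integer(n_train_days)
  if (!is_count(N) || N < 1L || N >= nd)
    stop("n_train_days must be in 1..", nd - 1L)
  budget <- budget %||% compute_sample_budget(study_day_counts(study))
  m_min <- budget$M_min
  q_train <- m_min %/% N
  q_test <- m_min %/% (nd - N)
  days <- as.integer(names(study))
  combos <- utils::combn(days, N, simplify = FALSE)
  cells <- expand.grid(repetition = seq_len(repetitions),
                       combination = seq_along(combos))
  cells$train_days <- vapply(combos[cells$combination], paste,
                             "", collapse = "+")
  cells$accuracy <- NA_real_
  cells$n_train <- cells$n_test <- NA_integer_
  row_ids <- character(0)
  for (i in seq_len(nrow(cells))) {
    r <- cells$repetition[i]; k <- cells$combination[i]
    res <- withr::with_seed(derive_seed(seed, "lndi", N, r, k), {
      tr_days <- combos[[k]]
      te_days <- setdiff(days, tr_days)
      tr <- rbind_feature_tables(lapply(tr_days, function(d) {
        tab <- study[[as.character(d)]]
        subset_rows(tab, stratified_sample_idx(tab, q_train))
      }))
      te <- rbind_feature_tables(lapply(te_days, function(d) {
        tab <- study[[as.character(d)]]
        subset_rows(tab, stratified_sample_idx(tab, q_test))
      }))
      if (!is.null(features)) {
        tr <- select_features(tr, features)
        te <- select_features(te, features)
      }
      list(acc = fit_predict(tr, te, cfg)$accuracy,
           n_train = nrow(tr), n_test = nrow(te),
           ids = c(tr$row_id, te$row_id))
    })
    cells$accuracy[i] <- res$acc
    cells$n_train[i] <- res$n_train
    cells$n_test[i] <- res$n_test
    row_ids <- union(row_ids, res$ids)
  }
  rep_means <- stats::aggregate(accuracy ~ repetition, cells, mean)
  out <- protocol_result("LNDI", cells, rep_means,
                         mean(rep_means$accuracy), repetitions, seed, cfg,
                         extra = list(N = N, budget = budget,
                                      n_combinations = length(combos),
                                      acc_lndi = mean(rep_means$accuracy),
                                      features = features,
                                      row_ids = row_ids))
  class(out) <- c("lndi_result", class(out))
  out
}

## ---- window width -------------------------------------------------------

window_width_epochs <- function(width, epoch_seconds = 5) {
  if (is.numeric(width)) return(as.integer(width))
  switch(width,
         "5s" = as.integer(1),
         "1min" = as.integer(60 / epoch_seconds),
         "5min" = as.integer(300 / epoch_seconds),
         "half" = NA_integer_,
         stop("unknown window width: ", width))
}

#' Window-width (temporal block) evaluation
#'
#' Within each day and class, consecutive temporal blocks of the given
#' width alternate between training and testing, starting with
#' training (a 1-min width means blocks of 12 five-second epochs);
#' `"half"` sends the first half of each day/class to training and the
#' second half to testing. Accuracy is computed per day and averaged.
#'
#' @param study a [subject_study()] whose rows carry within-day
#'   temporal order in the `epoch` column.
#' @param width `"5s"`, `"1min"`, `"5min"`, `"half"`, or a block width
#'   in epochs.
#' @param cfg a [classifier_config()].
#' @param epoch_seconds epoch duration used to convert widths
#'   (default 5).
#' @return a `protocol_result` with one cell per day. Deterministic:
#'   block alternation involves no randomness.
#' @export
window_width_evaluate <- function(study, width = c("5s", "1min", "5min", "half"),
                                  cfg = classifier_config(),
                                  epoch_seconds = 5) {
  if (is.character(width)) width <- match.arg(width)
  w <- window_width_epochs(width, epoch_seconds)
  days <- as.integer(names(study))
  cells <- data.frame(day = days, accuracy = NA_real_)
  for (i in seq_along(days)) {
    tab <- study[[as.character(days[i])]]
    tr_idx <- integer(0); te_idx <- integer(0)
    for (cl in sort(unique(tab$class))) {
      rows <- which(tab$class == cl)
      rows <- rows[order(tab$epoch[rows])]
      n <- length(rows)
      if (is.na(w)) {           # half-session
        n_tr <- ceiling(n / 2)
        if (n_tr >= n) stop("window width exceeds session length")
        tr_idx <- c(tr_idx, rows[seq_len(n_tr)])
        te_idx <- c(te_idx, rows[(n_tr + 1):n])
      } else {
        if (w >= n) stop("window width exceeds session length")
        block <- (seq_len(n) - 1L) %/% w
        tr_idx <- c(tr_idx, rows[block %% 2L == 0L])
        te_idx <- c(te_idx, rows[block %% 2L == 1L])
      }
    }
    cells$accuracy[i] <- fit_predict(subset_rows(tab, sort(tr_idx)),
                                     subset_rows(tab, sort(te_idx)),
                                     cfg)$accuracy
  }
  protocol_result("window-width", cells, cells, mean(cells$accuracy),
                  repetitions = 1L, seed = NA_integer_, cfg,
                  extra = list(width = width))
}

#' Sweep several window widths
#'
#' @param study a [subject_study()].
#' @param widths vector of widths accepted by [window_width_evaluate()].
#' @param cfg a [classifier_config()].
#' @param epoch_seconds epoch duration in seconds.
#' @return data frame with columns `width` and `accuracy` (day-averaged).
#' @export
window_width_sweep <- function(study,
                               widths = c("5s", "1min", "5min", "half"),
                               cfg = classifier_config(),
                               epoch_seconds = 5) {
  data.frame(
    width = widths,
    accuracy = vapply(widths, function(w)
      window_width_evaluate(study, w, cfg, epoch_seconds)$mean_accuracy, 0),
    row.names = NULL
  )
}
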