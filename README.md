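# eegdays

Cross-day calibration protocols and consensus feature selection for
EEG-based emotion classification.

## The problem

EEG band-power features drift from one recording day to the next
(electrode placement, impedance, baseline physiology), so an emotion
classifier trained on a single session degrades badly on data from
another day. `eegdays` implements the standard protocol toolkit for
quantifying and mitigating this:

* **Band-power features**: Welch's method (500-ms Hamming segments,
  50% overlap) integrated over six canonical bands — delta [0.5,4),
  theta [4,8), alpha [8,13), beta [13,30), low gamma [30,44), high
  gamma [44,100) Hz — per channel (60 channels × 6 bands = 360
  features), from 5-s epochs, with mastoid re-referencing and
  anti-alias decimation.
* **Calibration protocols** over a 5-day subject study
  Y¹…Y⁵ with day sizes M₁…M₅ and the sample budget
  M_min = ⌊min(Mᵢ)/12⌋ × 12:
  * *WDC* — within-day 80/20 split, 5 repetitions per day;
  * *SCDC* — train on one day (count-matched to WDC), test on each
    other day: a 5 × 4 grid;
  * *LNDI* — train on M_min/N rows from each of N days, test on
    M_min/(5−N) rows from each held-out day, over all C(5,N) day
    combinations, Acc_LNDI = mean over combinations and 10
    repetitions;
  * *window-width* — alternate temporal blocks (5 s / 1 min / 5 min /
    half-session) between train and test within each day.
* **Modified RFE**: per day-fold, recursively eliminate the feature
  whose individual removal loses the least accuracy; vote each fold's
  top-M list; features with ≥ 3 of 5 votes form the salient subset,
  validated on a held-back half under L1DI–L4DI. Contribution rates
  (fraction of subjects selecting each channel × band) aggregate
  subsets across subjects.
* **Synthetic multi-day generator** (signal level and feature level)
  with a log-linear model
  `log10 P = baseline + class_effect + day_effect (+ drift) + noise`,
  so the full pipeline is testable without any recordings.

The default classifier backend is an RBF-kernel regularized
least-squares machine with one-vs-one voting (log10 transform +
z-scoring on training statistics); linear-kernel and nearest-centroid
backends are injectable.

## Worked example

```r
library(eegdays)

# a drifting 5-day world: 4 channels x 6 bands, moderate day effects
model <- preset_moderate_drift(seed = 1)
study <- generate_feature_study(model, subject_id = 1)
study
#> <subject_study> 5 days, 24 features
#>   day 1: 60 epochs (negative=20, neutral=20, positive=20)
#>   day 2: 72 epochs (negative=24, neutral=24, positive=24)
#>   ...

compute_sample_budget(study_day_counts(study))$M_min
#> [1] 60

wdc_evaluate(study, seed = 1)$mean_accuracy
#> [1] 0.8553333
scdc_evaluate(study, seed = 1)$mean_accuracy
#> [1] 0.6300429
sapply(1:4, function(N) lndi_evaluate(study, N, seed = 1)$acc_lndi)
#> [1] 0.6383333 0.7356667 0.7506667 0.7670000
```

Within-day accuracy is high; training on one day and testing on the
others collapses it; pooling more training days recovers it
monotonically — the central phenomenon the LNDI protocol measures.
Feature selection and validation:

```r
halves <- split_selection_validation(study, seed = 1)
salient <- run_l4di_selection(halves$selection, M = 8, seed = 1)
salient
#> <salient_subset> 6 features selected (>= 3 of 5 votes, M = 8)
v <- validate_subset(halves$validation, salient, seed = 1)
v$comparison
#>   N   acc_all acc_subset
#> 1 1 0.6008333  0.7150000
#> 2 2 0.6416667  0.7879167
#> 3 3 0.6279167  0.7991667
#> 4 4 0.7291667  0.8358333
leakage_audit(salient, v)$disjoint
#> [1] TRUE
```

On this drifting world the consensus subset improves every LNDI
condition on the held-back validation half — the qualitative pattern
that motivates running the selection under the pooled-days (L4DI)
condition in the first place.

A command-line interface covers the same stages:

```sh
Rscript -e 'eegdays::eegdays_cli()' simulate --out study.csv --channels 8 --seed 1
Rscript -e 'eegdays::eegdays_cli()' evaluate --study study.csv --protocol lndi --n-days 4 --out cells.csv
```

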