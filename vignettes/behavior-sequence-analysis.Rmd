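---
title: "Analyzing home-cage behavior sequences along one light-dark cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing home-cage behavior sequences along one light-dark cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Video analysis of a singly housed rodent in its home cage yields a
*behavior sequence*: an ordered series of labeled intervals, one of 45 raw
labels per video frame, typically covering ~23 h around one lights-off
event. Mice are nocturnal, so almost any interesting group difference is
entangled with the light/dark cycle; and 45 behaviors resolved over many
time windows produce far more variables than animals, which invites
p-hacking if each variable is tested separately. `bseqlab` implements a
pipeline that (i) synchronizes every recording to the lights-off event,
(ii) pools behaviors into a small number of interpretable categories,
(iii) summarizes them over light-anchored time windows as variance-stabilized
proportions, and (iv) tests for group differences with a *single*
pre-registered multivariate test, complemented by explicitly exploratory
visualization and an optional machine-learning analysis with honest
permutation-based inference.

```{r setup}
library(bseqlab)
```

## Data model and metadata

Three CSV spreadsheets make a project machine-readable: a **master**
registry (one row per project: descriptive fields, the grouping column
name, and relative paths to everything else), an **experiment** file (one
row per test: animal, group value, recording start, data file and kind, an
optional `exclude` flag; any extra columns are carried through verbatim),
and a **lab** file (the light schedule as `"HH:MM"` times). `load_project()`
resolves the links; `validate_project()` returns a report of every violated
invariant rather than failing on the first, which is how corrupted or
misregistered files surface before any analysis runs.

Raw data come in three kinds. Event sequences use a documented TSV dialect
(`start_s`, `end_s`, `label`) because the vendor's binary export format is
proprietary; `read_events()` is the single import hook, so a future binary
converter only has to emit this dialect. Minute summaries store seconds per
behavior per minute (0–60; values in (60, 61] are clamped with a warning as
export rounding, anything larger is an error). Hour summaries are expanded
by using the hour value divided by 60 for each minute of that hour — exact
in aggregate, flat within the hour, which is why `check_consistency()`
takes a tolerance.

## Synchronization and time windows

`synchronize()` adds `bintodark`, the signed minutes of each minute's start
relative to the *anchor*: the first lights-off at or after the recording
start. Phase is `NIGHT` exactly when `bintodark mod 1440` falls within the
night length. Nine time windows are then resolved against the recording
(in `bintodark` minutes; lights off at 0, a 12-h night ends at 720):

| id | definition |
|----|-----------------------------------------|
| W1 | first 2 h of recording |
| W2 | last 2 h before nightfall, `[-120, 0)` |
| W3 | first 3 h of the night, `[0, 180)` |
| W4 | last 3 h of the night |
| W5 | first 3 h of the second day |
| W6 | 2 h before lights off to end of recording |
| W7 | whole day phase before lights-off |
| W8 | whole night phase |
| W9 | entire recording |

W1–W6 are the analysis windows one would pre-register; W7–W9 are the
overlapping trio spanning them. The composition of the trio was a genuinely
open design point: we chose day-phase / night-phase / whole-recording as
the smallest natural overlapping set, and `define_windows(overrides =)`
lets a user substitute any other definition. A window enters the analysis
only if *every* non-excluded animal fully covers it
(`available_windows()`), so each sample carries equal weight — recordings
of unequal length otherwise bias exactly the windows where circadian
effects live.

## Categories and features

The shipped mapping table (`category_scheme()`) pools the 45 raw labels
three ways: to 38 base categories (distance moved to its own slot, the
no-data and arousal channels discarded, the three drink and three eat zones
merged), to 18 categories that merge rarely occurring movement variants,
and to 10 categories matching what an open-source classifier can detect.
The table ships as a data file, checksum-pinned in the tests, so it can be
audited and extended without touching code.

For each test, window and category, the feature is
$\sqrt{t_{\text{category}} / t_{\text{window}}}$, the square root of the
proportion of the window's recorded behavior time spent in the category.
The square root stabilizes the variance of proportions without requiring
non-zero values (a log transform would). The denominator is the behavior
time actually recorded in the window, not the nominal window length, so a
dropped trailing minute cannot distort the proportions. With the
18-category scheme and all nine windows this is 162 variables per animal.

The distance channel cannot be computed from event sequences, only passed
through from minute summaries. When present it enters as the square root
of the window's share of the recording's total distance — the same [0, 1]
scale, but excluded from the per-window normalization because it is not a
time share. Its spread differs from the time-proportion variables, so
`drop_distance = TRUE` is recommended for the multivariate analysis and the
column is merely available, never required.

## The statistical strategy

**Confirmatory test.** `pca_group_test()` centers the columns (no
rescaling — the features already share one scale), projects onto the first
principal component, and compares PC1 scores across groups with a two-sided
Wilcoxon rank-sum test in its normal approximation with tie correction,
reporting $Z$, $p$ and the effect size $r = |Z|/\sqrt{n}$ (Kruskal–Wallis
for three groups; more than three are refused). One test, chosen before
looking at the data: this is the guard against testing 162 variables and
reporting the best.

**Exploratory picture.** `rf_select()` runs two sequential random forests
(500 trees, default feature subsampling, seeded): the first ranks all
variables by mean decrease in Gini impurity and keeps the top 20; the
second re-ranks those and keeps every variable whose importance, normalized
by the pass maximum, exceeds 0.95 — or the top 8, whichever set is larger.
The 0.95 threshold needed an interpretation, since a raw Gini decrease has
no intrinsic scale; normalizing by the second-pass maximum gives a
scale-free criterion and is flagged as interpretive in the documentation.
Ties are broken by variable name so selection is reproducible.
`ica_embed()` then runs FastICA on the selected variables and returns three
components for a 3-D view. This picture will *always* show structure — a
forest asked for discriminating variables among 162 will find some even
for shuffled labels — which is exactly why it is exploratory and the
p-value comes from the PCA route (the suite demonstrates this: on
label-shuffled data the median PCA p stays above 0.2 while the forest still
"selects" eight variables).

**Machine learning with honest inference.** `svm_validate()` trains an SVM
(radial or linear kernel, cost 1, features standardized on the training
fold) and validates by repeatedly holding out one animal per group when
groups have at most 15 animals (the boundary case 15 resolves to the
conservative small-n path), or by a single stratified one-third holdout
otherwise. Pooled predictions give accuracy and Cohen's kappa.
`permutation_pvalue()` repeats the entire validation with training labels
shuffled after each split (shuffling everything before the split is
available as `perm_scope = "all"`), counts permutations with accuracy at
least the observed one, and reports the point estimate $(k+1)/(n+1)$
together with a 95% Clopper–Pearson interval for $k/n$ — a p-value *range*
that is explicit about the resolution `n_perm` buys. Zero-variance
training-fold features are dropped before fitting, since standardization is
undefined for them.

## The synthetic generator

`simulate_project()` writes a complete fake project — metadata, event
TSVs, and minute summaries that are the exact minute aggregation of the
events plus a simulated distance channel (a noisy linear function of
walking seconds). Behavior is a semi-Markov chain over the 44 raw behavior
labels: states drawn from a propensity table (no immediate
self-transitions), dwell times exponential with per-label means rounded to
whole seconds. Defaults mirror a typical cohort: 11 animals per group,
1380-min recordings starting at 12:00 against a 19:00/07:00 light schedule,
so all nine windows are covered. Circadian structure is a single
multiplier: active labels are up-weighted and the four resting labels
down-weighted at night (factor 2), reversed by day.

The default planted group effect is a night activity phenotype: the second
group's walking propensities are doubled and its sleep propensity reduced
to 0.6 during NIGHT. A shift confined to walking alone is strong
variable-by-variable but nearly invisible to a variance-based first
principal component, because walking is a minor part of the time budget and
PC1 is owned by sampling variability in the dominant categories; pairing it
with a shift in the dominant rest category makes the planted effect strong
in the multivariate sense too, which is what the power checks require. Any
other effect (label, phase, multiplier) can be injected via `effect =`.

What the generator does *not* emulate: individual baseline differences
between animals (all animals share one parameter set, so between-animal
variance is pure chain-sampling noise), realistic transition structure
(draws are independent of the previous state beyond the no-repeat rule),
ultradian rhythms, and measurement artifacts other than the three injectable
corruption modes. Green tests therefore certify the pipeline's arithmetic
and its statistical calibration under a known model — not that any
particular biological effect is detectable in real recordings.

`corrupt_project()` plants a known defect in one animal's minute summary
(scaling one category, displacing minutes, or truncating the file) and
repoints the metadata at the corrupted file, emulating a bad spreadsheet
export; the consistency checker must then flag it against the untouched
event file.

## Numerical choices and test sizing

Tolerances: per-window squared features must sum to 1 within 1e-6;
minute-level consistency uses a 1-s default tolerance per category per
minute (export rounding); the ICA falls back to the available rank with a
warning when the centered data have rank below three. All stochastic steps
take explicit integer seeds and are bit-reproducible.

The calibration and power suites are sized for a single CPU: 100–200 null
replicates for the PCA type-I check (small Gaussian matrices and reduced
synthetic cohorts of 4 animals per group over 12-h recordings), 100 null
runs at 49 permutations and 10 two-out repeats for the permutation p-value
calibration (the permutation p is discrete, so at small settings it is
conservative rather than exactly uniform — the checks bound the rejection
rate accordingly), 100 full-size default cohorts for the PC1 power check,
and 100 strong-shift runs at 80 permutations for the SVM power check (80
permutations is the smallest cloud whose Clopper–Pearson upper bound can
fall below 0.05).

## A worked example

```{r, eval = FALSE}
dir <- tempfile()
pr <- simulate_project(sim_config(seed = 1), dir)
res <- run_analysis(pr$master_file, pr$project_id,
                    do_ml = TRUE, n_perm = 100, seed = 1)
res$pca_test
res$selection
res$ml
```

`run_analysis()` writes a markdown report plus CSV artifacts (ICA
coordinates, PC1 scores, permutation accuracies) into a versioned
`bseqlab_<version>/` folder and derived data (synchronized minute
summaries, the feature matrix) into an unversioned `bseqlab/` folder, never
touching the input files. Hourly activity summaries
(`hourly_summary()`, `plot_hourly()`) and behavior-transition context
around a focal label (`transition_context()`) support the explorative side;
`pool_projects()` concatenates feature matrices across projects and returns
first-component scores against animal age for meta-analysis, rejecting —
with the reason recorded — projects that lack birth dates or the requested
windows.

## Known limitations

More than three groups are deliberately unsupported (split into pairs
upstream). The distance channel is pass-through only. The L1-regularized
regression sometimes used for this kind of cohort is out of scope, as are
interactive dashboards; the markdown report and CSV artifacts are the
interface. The hour-summary path inherits the source's within-hour
flatness: synchronization to lights-off is then only hour-precise.
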