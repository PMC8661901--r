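# bseqlab

Analysis of home-cage behavior sequences of singly housed rodents along one
light-dark cycle, for behavioral neuroscientists who get their data from
frame-wise video classification (a 45-label ethogram plus a distance
channel) and want group comparisons that respect circadian structure
without p-hacking.

## What it does

A recording is an ordered series of labeled behavior intervals spanning
~23 h around one lights-off event. `bseqlab`:

1. reads event sequences (a documented TSV dialect), minute summaries, or
   hour summaries, linked through a three-spreadsheet metadata schema
   (master registry, per-test experiment file, lab light schedule) that
   makes projects machine-readable and validatable;
2. synchronizes each recording to the lights-off anchor (`bintodark`,
   DAY/NIGHT phase) and pools the 45 raw labels to 38, 18, or 10 behavior
   categories via a shipped, auditable mapping table;
3. builds features over nine light-anchored time windows: for category
   $c$ and window $w$, $x_{cw} = \sqrt{t_{cw} / t_w}$, the square root of
   the proportion of window time spent in the category (up to
   18 × 9 = 162 variables per animal) — variance-stabilizing without
   requiring non-zero values;
4. tests for group differences with one pre-registered test: PC1 of the
   column-centered feature matrix, compared across groups by a two-sided
   rank-sum test reported as $Z$, $p$ and effect size $r = |Z|/\sqrt{n}$;
5. complements it with explicitly exploratory views — double
   random-forest variable selection (top 20 by Gini importance, then the
   best 8–20) feeding a 3-component ICA embedding, hourly activity
   curves, behavior-transition context around a focal label — and an
   optional SVM analysis (two-out validation below 16 animals per group,
   independent holdout above) with Cohen's kappa and a permutation null
   summarized as a Clopper–Pearson p-value range;
6. generates complete synthetic projects (semi-Markov behavior chains
   with circadian modulation and injectable group effects or file
   corruptions), so every pipeline stage is testable without any data
   download.

## Worked example

```r
library(bseqlab)
dir <- tempfile()
pr <- simulate_project(sim_config(seed = 1), dir)   # 2 x 11 animals, 23 h each
res <- run_analysis(pr$master_file, pr$project_id,
                    do_ml = TRUE, n_perm = 100, seed = 1)
res$pca_test
#> <group_test> Wilcoxon rank-sum (normal approximation, tie-corrected)
#>   PC1 explains 25.7% of variance; Z = 3.973 , p = 7.105e-05, r = Z/sqrt(n) = 0.847
res$selection
#> <rf_selection> 8 of 162 variables (seed 1):
#>    Distance_traveled__W6, Distance_traveled__W8, Immobile__W6, Immobile__W8,
#>    Immobile__W9, Walk__W4, Walk__W6, Walk__W8
res$ml
#> <ml_result> radial SVM, two_out validation
#>   accuracy = 0.925 , kappa = 0.85
#>   p = 0.0099  range [ 0 , 0.0362 ] from 100 permutations
```

The generator's default cohort plants a night activity phenotype in the
second group (walking up, sleep down). The confirmatory PCA test detects
it decisively (p < 1e-4, large effect size); the forest selects exactly
the walk/immobility/distance variables in the night-containing windows;
and the SVM separates the groups better than all 100 label permutations
(the p-value range `[0, 0.036]` is the 95% binomial interval on the
exceedance fraction 0/100). `run_analysis()` writes a markdown report and
CSV artifacts into `bseqlab_<version>/` and derived data (synchronized
minute summaries, the feature matrix) into `bseqlab/`.

A thin command-line wrapper is included at `inst/cli/bseqlab.R`
(`validate`, `simulate`, `analyze`, `hourly`, `transitions` subcommands).
The methods vignette (`vignettes/behavior-sequence-analysis.Rmd`) documents
the model, the window definitions, the parameter choices and what the
synthetic generator does and does not emulate.

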