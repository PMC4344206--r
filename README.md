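# pascalc

Pairwise Agonist Scanning (PAS) and an ensemble "calcium calculator" for
platelet signaling, in R.

Platelet activation integrates signals from ADP (P2Y1/P2Y12), collagen
mimetics such as convulxin (GPVI), thrombin (PAR1/PAR4) and the
thromboxane mimetic U46619 (TP), under restraint by prostacyclin mimetics
(iloprost, cAMP) and NO donors (GSNO, cGMP). All of these converge on
intracellular calcium mobilization, measured as the baseline-normalized
fluorescence F/F0 of dye-loaded platelets. PAS measures calcium responses
to **all single agonists and all agonist pairs** over a dose grid in EC50
multiples (0.1x, 1x, 10x — 154 conditions for six agonists, including a
buffer condition), trains dynamic neural networks on those traces, and
uses the trained ensemble to predict responses to conditions it never saw:
trinary, higher-order (4–6 agonists) and sequential stimulations.

The package implements, with tests against known ground truth:

* **Designs** — pairwise (154), trinary (173), the 3,402-condition
  higher-order space with stratified 45-condition sampling (16/19/10 by
  order), and 54 two-dispense sequential schedules; canonical labels,
  TSV round trip.
* **Synthetic donors** — a phenomenological F/F0 simulator with
  agonist-specific kinetics, multiplicative inhibition, pairwise crosstalk
  of configurable sign, output saturation, donor variability and noise.
* **Preprocessing** — baseline normalization, replicate averaging,
  resampling from the 2.5 s read grid to a 1 s model grid, trapezoidal
  AUC of baseline excess.
* **Dynamic networks** — a 12-hidden-node network over current agonist
  inputs plus its own output at lags {1,2,4,8,16,32,64,128} s, trained
  teacher-forced (condition-level 90/10 split, early stopping,
  best-validation restore) and evaluated closed-loop.
* **Ensembles** — multi-donor x multi-seed bags with pointwise-mean
  prediction, min/max envelopes, IQR-fence pruning, JSON archives.
* **Synergy metrics** — normalized synergy scores
  `S_n = (A_1..n − sum_i A_i) / max|A_1..n − sum_i A_i|` in [−1, 1],
  percent inhibition, four-parameter Hill EC50 fits, pooled Pearson R and
  between-donor variation summaries.

## Worked example

```r
library(pascalc)

panel  <- default_agonist_panel()          # six agonists with EC50s
design <- enumerate_pairwise(panel, dose_grid())
nrow(design)
#> [1] 154
head(design$label, 4)
#> [1] "null"    "ADP:0.1" "ADP:1"   "ADP:10"

# simulate one synthetic donor's PAS experiment (2 replicates, averaged)
time_s <- model_time_grid()                # -20 s baseline ... 210 s, 1 s grid
donor  <- sample_donor(default_donor_params(), seed = 1)
experiment <- average_experiment(simulate_experiment(
  donor, design_schedules(design, panel), time_s,
  replicates = 2, seed = 1, donor_id = "D01", design = design))

synergy <- synergy_vector(experiment)      # one score per pair condition
nrow(synergy)
#> [1] 135
synergy[order(-synergy$score), c("label", "score")][1:3, ]
#>                 label     score
#> 51  CVX:1|Thrombin:10 0.3823968
#> 54 CVX:10|Thrombin:10 0.3772892
#> 53  CVX:10|Thrombin:1 0.3637595
synergy[order(synergy$score), c("label", "score")][1:3, ]
#>                      label      score
#> 72      CVX:10|Iloprost:10 -1.0000000
#> 71       CVX:10|Iloprost:1 -0.9447331
#> 99 Thrombin:10|Iloprost:10 -0.7460091
```

The strongest synergies sit on the convulxin–thrombin pair (the coupled
pair of the default donor model) and the strongest antagonisms on
high-dose iloprost pairs, with the single most antagonistic condition
pinned at −1 by the normalization. Iloprost's potency shows up directly
as percent inhibition:

```r
aucs <- experiment_aucs(experiment)
percent_inhibition(aucs[["CVX:1"]], aucs[["CVX:1|Iloprost:1"]])
#> [1] 94.7
```

Training an ensemble and predicting a held-out design:

```r
spec <- nn_spec(n_inputs = nrow(panel), max_epochs = 300, patience = 300)
ens  <- train_ensemble(list(experiment), n_per_donor = 4,
                       base_seed = 1, spec = spec)
trinary <- enumerate_trinary(panel, dose_grid(c(0.1, 1)))
pred <- predict_ensemble(ens, design_schedules(trinary, panel), time_s)
str(pred$mean)        # time x 173 matrix of predicted F/F0
```

`run_pipeline(pas_config(), "out/")` chains
design → simulate → train → predict → synergy and writes every artifact
(condition tables, trace CSVs, an ensemble archive, synergy TSVs, a JSON
manifest) under `out/`. A thin command-line wrapper lives at
`inst/cli/pas.R`.

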