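---
title: "Pairwise Agonist Scanning and the ensemble calcium calculator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise Agonist Scanning and the ensemble calcium calculator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pascalc)
```

## The problem

Platelet activation is driven by several receptor pathways — ADP on
P2Y1/P2Y12, collagen mimetics such as convulxin on GPVI, thrombin on
PAR1/PAR4, the thromboxane mimetic U46619 on TP — and restrained by
prostacyclin mimetics (iloprost, via cAMP) and NO donors (GSNO, via cGMP).
All of these converge on intracellular calcium mobilization, which makes
the dynamic calcium trace a global readout of platelet activation state.
Because the pathways cross-talk, the response to an agonist combination is
not the sum of the individual responses, and a mechanistic ODE model of the
full network would need hundreds of poorly known kinetic parameters.

Pairwise Agonist Scanning (PAS) takes a data-driven route instead: measure
calcium responses to *all* single agonists and *all* agonist pairs across a
dose grid expressed in EC50 multiples (0.1x, 1x, 10x), train a dynamic
neural network on those traces, and let the trained model extrapolate to
higher-order combinations. `pascalc` implements this workflow end to end,
with a synthetic-donor simulator standing in for plate-reader data so that
every stage — training, closed-loop prediction, synergy recovery — can be
tested against a known ground truth.

## Stimulation designs

For a panel of $n$ agonists and a dose grid of $g$ multipliers the package
enumerates:

* **pairwise**: all $ng$ singles, all $\binom{n}{2}g^2$ pairs and one null
  (buffer) condition — $6 \cdot 3 + 15 \cdot 9 + 1 = 154$ conditions for
  the default panel;
* **trinary**: singles plus all three-agonist combinations (no pairs); at
  two doses this is $12 + 160 + 1 = 173$ conditions;
* **higher order**: all conditions of order 4–6, a
  $\sum_k \binom{6}{k} 3^k = 3402$-condition space, sampled in fixed
  stratum sizes (16, 19, 10) to the 45-condition panel actually run;
* **sequential**: ordered dispenses of distinct agonists; two dispenses of
  three agonists over three doses give $3 \cdot 2 \cdot 3^2 = 54$
  schedules (second dispense at 300 s, 780 s horizon).

Conditions are identified by canonical labels (`"ADP:1|CVX:0.1"`) that act
as stable join keys across files. Doses add across dispenses; no dilution
correction is applied.

## The synthetic donor model

The simulator is phenomenological, not mechanistic. Each activator $i$
dispensed at time $t_0$ with dose $d$ (in EC50 multiples) contributes a
drive

$$ r_i(t) = A_i(d)\,\bigl(1 - e^{-(t-t_0)/\tau_r}\bigr)
   \bigl(s + (1-s)\,e^{-(t-t_0)/\tau_d}\bigr), \qquad
   A_i(d) = a_{\max}\frac{d^h}{d^h + 1}, $$

with rise constant $\tau_r$, decay constant $\tau_d$ and sustained
fraction $s$. Crosstalk enters through a symmetric matrix $\gamma$ acting
on geometric means, inhibitors act multiplicatively on the total drive,
and the output saturates:

$$ D(t) = \Bigl[\sum_i r_i + \sum_{i<j}\gamma_{ij}\sqrt{r_i r_j}\Bigr]
   \prod_k \frac{1}{1 + p_k d_k}, \qquad
   F/F_0(t) = 1 + f_{\max}\frac{D}{D + K} + \varepsilon. $$

The geometric-mean coupling makes the crosstalk term vanish whenever
either agonist is absent, which is exactly the property the synergy score
measures. Inhibition on the *total* drive mirrors the global
cAMP/cGMP action of iloprost and GSNO. Noise $\varepsilon$ is i.i.d.
Gaussian on $F/F_0$; donors differ by independent lognormal factors (unit
mean, CV `donor_cv`) on each $a_{\max}$.

Default parameters encode the qualitative kinetics the assay shows:
fast-transient ADP and U46619 ($\tau_r \approx 4$–5 s, low sustained
fraction), slow-sustained convulxin ($\tau_r = 35$ s, $s = 0.85$),
fast-sustained thrombin, iloprost a far more potent inhibitor than GSNO
(potency 20 vs 0.3). The crosstalk default couples convulxin and thrombin
($\gamma = 1.2$) — the pair with the strongest reported synergy — and the
saturation scale ($K = 10$, $f_{\max} = 4$) is calibrated so the
noise-free score structure reproduces the reported phenotype: a maximum
pairwise score near $+0.4$ on the convulxin–thrombin pair, a slightly
negative mean pairwise score, a most-antagonistic score of $-1$ on a
high-dose iloprost pair, and strongly negative higher-order scores from
saturation. Defaults `donor_cv = 0.15` and `noise_sd = 0.02` are fixture
choices — plausible for replicate plate-reader wells, but not a claim
about any cohort.

What the simulator deliberately omits: store depletion/SOCE dynamics,
autocrine ADP/thromboxane feedback (excluded in the assay itself),
photobleaching and drift, receptor desensitization, and any per-agonist
temporal structure of inhibition. Passing tests on synthetic donors
therefore demonstrate that the pipeline recovers what it assumes — they do
not validate the biology of real donor traces.

## Preprocessing conventions

Raw fluorescence is normalized by the mean of the 20 s pre-dispense
baseline, replicate wells are averaged pointwise before training, and the
2.5 s read grid is linearly interpolated onto a 1 s model grid so the lag
set maps to integer sample offsets. The area under the curve integrates
$F/F_0 - 1$ (baseline excess) trapezoidally over the full 210 s
post-dispense window: this makes the null condition integrate to exactly
zero so that additivity corresponds to a zero synergy numerator, and
negative excursions are kept so the integral stays linear. Whether the
original protocol subtracted baseline before integrating is not stated;
the choice only shifts raw deviations, not the additive zero point.

## The dynamic network

One calculator unit is a single-hidden-layer network (12 tanh nodes,
linear output) over 14 inputs: six dose channels and eight feedback taps
of its own output at lags {1, 2, 4, 8, 16, 32, 64, 128} s. "Two-layer,
12-node" follows the older toolbox convention that counts the output
layer. Doses are encoded as $\log_{10}(1+d)/\log_{10}(11)$ so the three
dose decades stay separable without saturating the sigmoid; all features
and the target are affinely standardized with statistics of the training
rows.

Training is teacher-forced: the *measured* trace fills the lag slots, the
target is the next measured value, and history before the first dispense
is padded at baseline 1.0. The split into training and validation (90/10)
is done at *condition* granularity so lagged samples of one trace can
never leak across the split. The mean-squared error is minimized by
full-batch resilient backpropagation (Rprop, step adaptation 1.2/0.7,
initial step 0.01, step cap 1); the run is fully determined by the seed.
Early stopping monitors the validation MSE and restores the best-validation
weights. The patience default of 5 epochs matches the original protocol,
in which one epoch was a Levenberg–Marquardt step; an Rprop epoch is a
much smaller move, so the pipeline configurations train a fixed budget of
300 epochs (patience set equal to the cap), which keeps per-member
training around two to five seconds.

Prediction is closed-loop: the one-step map is iterated with its own past
outputs in the lag slots, clipped below at 0. The tanh hidden layer makes
the output inherently bounded, so closed-loop prediction cannot diverge.
Teacher-forced one-step error is expected to lower-bound closed-loop
error, and the test suite asserts this on fixtures.

## The ensemble

The calculator proper is a bag of networks: several seeds per donor
(distinct initializations and splits), member seeds derived from a
deterministic hash of (base seed, donor id, index) so adding donors never
perturbs existing members. Predictions are averaged pointwise; for squared
error, Jensen's inequality guarantees the ensemble mean is at least as
accurate as the average member, and the suite asserts this on every
synthetic evaluation. The min/max envelope over members measures
intra-ensemble variation. Members can be pruned by Tukey's IQR rule
(closed-loop MSE above $Q_3 + 1.5\,\mathrm{IQR}$ on a validation
experiment); the fence multiplier 1.5 is the conventional choice, as the
original method names only "the IQR outlier detection method". At least
one member is always retained.

## Synergy scores

For a combined condition of order $n$ with per-condition AUCs $A$,

$$ S_n = \frac{A_{1\ldots n} - \sum_{i=1}^n A_i}
  {\max\bigl|A_{1\ldots n} - \sum_i A_i\bigr|}, $$

where the maximum runs over all combined conditions of the experiment, so
$S_n \in [-1, 1]$, exactly one score reaches $\pm 1$, and signs are
preserved. Normalization is scoped per experiment-design evaluation;
cross-design comparisons should use raw deviations. The pairwise design
yields 135 scores, the trinary design 160. Percent inhibition is the
AUC ratio $100(1 - A_{+\mathrm{inh}}/A_{\mathrm{agonist}})$, with negative
values reporting potentiation. EC50s are estimated by least-squares
four-parameter Hill fits of AUC against dose, multi-started over Hill
slopes {0.5, 1, 2, 4} to avoid slope-local minima.

## Problem sizes and numerical choices

The shipped configurations use five synthetic donors, two replicates,
four networks per donor and a 300-epoch budget; with the 154-condition
pairwise training design this trains in roughly two minutes and predicts
the 173-condition trinary holdout in seconds. Degenerate inputs fail
loudly and early: empty panels or grids, non-uniform time grids,
nonpositive baselines, traces shorter than the longest lag, flat
dose-response data, zero-variance correlation inputs. Ties in the synergy
normalization need no tie-break (any maximizer gives the same constant).
If every raw deviation is zero, all scores are reported as zero rather
than dividing by zero.

## Limitations

* The simulator's crosstalk is stationary and pairwise; it cannot emulate
  order-specific interactions or time-dependent inhibition kinetics.
* The network sees cumulative dispensed dose, not concentration decay, so
  washout or degradation of agonists is out of scope.
* Closed-loop accuracy on real donor data depends on assay features the
  synthetic donors do not model; the recovery results here bound what the
  code can do under its own assumptions, nothing more.
* Import of the originally deposited MATLAB trace archives is not
  provided; trace matrices are exchanged as CSV/TSV instead.
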