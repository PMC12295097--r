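---
title: "Methods: functional principal component forecasting of regional workforce panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional principal component forecasting of regional workforce panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The package analyses a rectangular panel of strictly positive annual counts
$y_t(x)$ — in the motivating application, the number of doctors in region $x$
and year $t$. Counts are modelled on the natural-log scale as a smooth
low-rank structure plus error:

$$\log y_t(x) = \mu(x) + \sum_{j=1}^{J} \beta_j(x)\,\kappa_j(t) + e_t(x),$$

where $\mu(x)$ is the per-region mean over the training years, the $\beta_j$
are orthonormal loading vectors over regions ("basis functions"), and the
scores $\kappa_j(t)$ are time series. This is the functional-data view in
which each year is a curve over the regional index; because regions are an
*unordered discrete* index, no smoothing over $x$ is meaningful and the basis
is extracted directly from the data: $\beta_j$ are the leading eigenvectors
of the covariance of the centred year-curves (equivalently, left singular
vectors of the centred $R \times T$ log matrix), and $\kappa_j(t)$ is the
projection of year $t$'s centred curve onto $\beta_j$. These are empirical
orthogonal functions; penalised or sparse functional PCA variants are
deliberately out of scope.

Forecasting reduces to forecasting the $J$ univariate score series and
mapping back through the fixed basis:

$$\hat y_{T+h}(x) = \exp\Big\{\mu(x) + \sum_{j=1}^J \hat\kappa_j(T+h)\,\beta_j(x)\Big\}.$$

Because every region's forecast flows through the same low-dimensional
scores, regional forecasts are *coherent*: they cannot drift apart in ways
the historical covariance structure does not support.

Assumptions worth keeping in mind: the log transform presumes
multiplicative errors and strictly positive counts; the decomposition
presumes that a few components carry most of the variance (on the reference
conditions the trend component alone carries ~95%); and score forecasting
presumes the scores' temporal dynamics are stable enough to extrapolate.

### Numerical conventions

* Natural log throughout; forecasts are exponentiated at the end.
* Covariance uses divisor $T$; explained-variance shares are eigenvalue
  ratios, so the divisor choice cancels.
* Sign convention: each basis column is flipped so its largest-magnitude
  entry is positive (the score column flips with it). This resolves the
  inherent sign indeterminacy and keeps score series continuous across
  cross-validation refits.
* `J = 3` by default; an optional cumulative-share threshold can trim (never
  grow) the retained set.
* A panel with zero centred variance raises a degenerate-data error rather
  than returning an arbitrary basis.

## Score forecasting

Two interchangeable engines forecast each score series independently (one
model per component — a joint multivariate model is out of scope).

**Automatic ARIMA.** The differencing order $d$ is the smallest order at
which the KPSS test no longer rejects level stationarity at the 5% level
(Bartlett-window long-run variance, lag truncation
$\lfloor 4(n/100)^{1/4}\rfloor$); KPSS is implemented in the package because
no unit-root testing package is part of its dependency set. Given $d$, the
$(p, q)$ pair minimises AICc over the exhaustive grid $[0..5] \times [0..5]$
(the series are short, so the grid is cheap and stepwise search is
unnecessary), with ties resolved towards smaller $p+q$, then smaller $p$.
Models include a mean when $d = 0$. When $d = 1$ the grid additionally tries
a linear drift regressor and keeps it if the criterion prefers it: without a
drift candidate, trend-dominated score series (the dominant pattern in this
application) would be forecast flat, which is also why mainstream automatic
ARIMA selectors include drift candidates. A series whose $d$-th difference
is numerically constant is a pure polynomial trend and is continued in
closed form. Fitting and prediction are delegated to `stats::arima`
(CSS-ML).

**LSTM.** A deliberately small recurrent network — one LSTM layer (50
units), a dropout layer (rate 0.2) on its output, and a linear head —
trained with Adam (learning rate 0.001) on mean squared error. The
look-back window is 3 years, giving $T - 3$ overlapping supervised pairs.
Because no deep-learning framework is part of the package's dependency set,
the network (forward pass, backpropagation through time, Adam, dropout) is
implemented in compiled code with a private deterministic RNG: a seed fully
determines initial weights, per-epoch shuffling, dropout masks and
forecasts, bit for bit.

Choices the LSTM needed that are genuinely open:

* **Scaling**: each score series is min-max scaled to $[0,1]$ before
  training and forecasts are inverse-scaled; standard for small-magnitude
  recurrent regression and bounded gradients.
* **Epochs 200, batch size 4, no early stopping**: a ~22-pair training set
  trains in well under a second while reaching the constant-series fixed
  point; early stopping would add a validation split the short series
  cannot afford.
* **Multi-step forecasts are recursive** (each prediction is appended to the
  window), matching the one-step structure of the validation design.
* A known limitation, documented by the test suite's empirical band: on an
  exactly linear series the one-step forecast must extrapolate slightly
  beyond the scaled training range, where the saturating LSTM
  nonlinearities bias predictions low by a few percent of the series range
  for unlucky training seeds (median error well under 5% of the range,
  worst observed under 8% across 20 seeds at the default configuration).

## Validation

**Rolling-origin expanding-window CV.** The first fold trains on the first
16 years and forecasts the 17th; each later fold extends the training window
by one year, until the final year has been tested — 9 folds on a 25-year
panel. The decomposition is refit on each fold's training window, scores are
forecast one step, the year-curve is reconstructed and exponentiated, and
absolute percentage errors $\mathrm{APE} = |A - F|/A \times 100$ are recorded
per region. MAPE aggregates are plain means over the APE grid (per region,
per test year, overall); when every fold covers every region the overall
cell-mean equals the mean of region-means. A failing fold raises — aggregates
are never silently computed on a subset.

**Permutation test.** The observed LSTM CV MAPE is compared against `B`
replicates in which each fold's training score matrix has its *rows* (years)
randomly permuted before the supervised windows are built and the LSTM
retrained; the decomposition is left intact, so exactly the forecaster's
access to temporal order is destroyed. One permutation is applied jointly to
all components, preserving cross-component alignment (an independent
per-component permutation is available behind a flag). The p-value is the
fraction of permuted MAPEs at or below the observed MAPE (`count/B`). This
convention can report an exact zero, which a `(count+1)/(B+1)` convention
cannot; it is anti-conservative and is labelled as such here. The 95%
interval reported alongside is the 2.5/97.5 percentile range of the permuted
MAPEs.

## Final forecasts and uncertainty

For the final forecast the decomposition is fit on the full panel and scores
are forecast to the horizon (9 years by default). With the LSTM engine,
uncertainty comes from Monte-Carlo dropout: 100 forward passes with dropout
active at inference, each pass forecasting a full recursive score path with
an independent seeded mask stream. Each pass's score path is reconstructed
to counts *before* aggregation, so the intervals inherit the cross-region
coherence of the basis; the point forecast is the mean over passes (median
optional) and the interval bounds are the 2.5/97.5 percentiles. Percentile
rather than Gaussian intervals are used because pass distributions are
mildly skewed after exponentiation. Two facts about these intervals that
the tests encode: with dropout rate 0 all passes coincide and the intervals
have zero width; and because the forecast is recursive, pass variance grows
with the horizon, so the MC *mean* at far horizons carries an error of
order $\mathrm{sd}/\sqrt{\text{passes}}$ — run-to-run agreement should be
judged against that scale, not a fixed percentage.

The ARIMA engine also provides final forecasts, with analytic normal
intervals on the log scale (score forecast variances propagated through the
squared loadings, components treated as independent), mainly for method
comparison.

## The synthetic-data generator

The generator exists so every stage is testable with known ground truth. It
draws orthonormal loadings (first component sign-constrained: all regions
positive except one designated counter-trend region), builds score series as
a linear trend plus AR(1) deviations (coefficient 0.6 by default), centres
and orthogonalises them over time, rescales their energies to the requested
variance shares, adds i.i.d. Gaussian log-scale noise and exponentiates.
The defaults mirror the reference study conditions: 16 regions, 25 years
starting in 2000, shares (94.7, 2.0, 1.3)%, and a region-8 analogue with a
negative trend loading. Region means default to a log-linear ladder from
about 12,000 down to about 1,500 — a realistic spread for regional physician
headcounts. Anomaly injection (single-year spikes; dip-and-rebound pairs)
emulates the reporting artefacts and one-off hiring events seen in real
panels.

Two generator conventions matter for interpretation:

* Score series are mean-centred over time, so $\mu(x)$ is identifiable as
  the time-mean and is recovered exactly in the noiseless case.
* When `noise_sd` is left `NULL`, it is calibrated so the *expected* noise
  energy equals the unstructured remainder $1 - \sum_j s_j$ of the total
  centred variance; the requested shares are then shares of total variance
  in expectation. Sample eigen-shares still exceed the design share
  slightly, because each retained eigendirection also absorbs the noise
  projected onto it; to first order the expected recovered leading share is
  $(\mathrm{ss}_1 + \sigma^2 (T-1)) / (\sum_j \mathrm{ss}_j + \sigma^2 R (T-1))$,
  which is what the recovery tests compare against.

What the generator does *not* emulate: demographic covariates (population,
vacancy counts), policy interventions, reporting-error structure beyond the
two anomaly kinds, and cross-sectional error correlation. Passing tests on
synthetic panels therefore certify the pipeline's mechanics and its
behaviour under the assumed model — not forecast accuracy on any particular
real panel.

## Problem sizes used by the checks

The automated checks run the full pipeline at the reference size (16 × 25,
$J = 3$, 9 CV folds) for the decomposition, both CV engines and the final
forecast; the permutation test runs at $B = 20$; unit-level properties use
smaller panels (4–8 regions, 8–14 years) and a reduced network (20 units, 60
epochs) where the property being tested does not depend on the full
configuration.

## Known limitations

* Corrections (interpolation/overrides) operate on the raw count scale, as
  reporting errors are stated in counts; corrected cells may be non-integer
  and are not rounded.
* The KPSS-based differencing decision uses the 5% critical value from the
  standard table; other significance levels are limited to tabulated ones.
* The LSTM's recursive forecasts inherit extrapolation bias near the edge of
  the scaled training range (see above).
* The permutation p-value convention can report exactly 0; treat it as
  "below $1/B$", not as a literal impossibility.
* Score components are forecast independently; any cross-component
  dependence in the dynamics is ignored by both engines.
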