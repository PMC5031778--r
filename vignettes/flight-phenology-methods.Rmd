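---
title: "Degree-day flight phenology models for codling moth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day flight phenology models for codling moth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmflight)
library(dplyr)
```

## The problem

Codling moth (*Cydia pomonella*) is the key internal fruit-feeding pest of
apple. Growers time insecticide applications against it with phenology
models that predict, from accumulated thermal time, what fraction of the
season's adult flight has occurred. The long-serving reference is the PETE
model (prediction extension timing estimator, a 1970s multi-species
phenology system); locally fitted alternatives — here called PCM
(Pennsylvania codling moth) models — re-estimate the flight curve from
pheromone-trap captures in the orchards where the predictions will be used.
Local populations can fly later than the reference predicts (insecticide
resistance, local ecotypes, diapause variability), and commercial and
abandoned orchards can differ from each other, so the package's job is to
make the whole chain reproducible: thermal time, flight onset, generation
partitioning, curve fitting, model comparison, and validation.

## The model

Flight is modelled as a logistic function of cumulative degree-days $X$
from *biofix* (the first sustained male capture):

$$E(Y) = \frac{e^{\beta_0 + \beta_1 X}}{1 + e^{\beta_0 + \beta_1 X}},$$

where $Y$ is the cumulative proportion of the generation's capture. The
logit transform $p' = \log_e[p/(1-p)]$ linearizes the curve, and
$(\beta_0, \beta_1)$ are estimated by unweighted ordinary least squares of
$p'$ on $X$ (`fit_flight_model()`). Because the logit is the exact inverse
of the logistic, noise-free logistic data are recovered to machine
precision — the basis of the package's round-trip checks.

```{r roundtrip}
pete1 <- pete_flight_model(1)         # published reference, first flight
dd <- seq(dd_at_fraction(pete1, 0.01), dd_at_fraction(pete1, 0.99),
          length.out = 40)
curve <- tibble::tibble(dd = dd, cum_prop = predict(pete1, dd))
coef(fit_flight_model(curve))         # recovers (-3.517, 0.012) exactly
```

## Thermal time

`daily_degree_days()` implements the simple-average method with a
horizontal cutoff: both daily extremes are clamped into the
`[lower, upper]` threshold band (defaults 10 °C and 31 °C, the standard
codling-moth thresholds), averaged, and the lower threshold subtracted,
floored at zero. A day can therefore contribute at most
`upper - lower` = 21 °C-days. The horizontal-cutoff rule is the
conventional companion of simple averaging; the rule sits behind a single
function so a vertical-cutoff variant could be added without touching the
rest of the pipeline.

`accumulate_degree_days()` anchors the running total at the biofix: the
anchor day contributes zero and accumulation starts the day after, making
the anchor the exact origin $X = 0$ of every flight curve. Whether
accumulation should begin on or after the biofix day is genuinely
ambiguous in field practice; the day-after convention was chosen so that
"zero thermal time has elapsed at biofix" holds exactly, and it is
recorded in the result's attributes. Missing days are a hard error by
default; runs of up to `max_gap` days may be filled by linear
interpolation of the daily extremes, with a message naming the filled
dates.

## Biofix and generation partitioning

"First sustained capture" is operationalized as the earliest check with at
least `min_count` moths (default 1) confirmed by at least one further
capture within the next `confirm_within` checks (default 2); an isolated
early moth does not anchor the season. Both knobs are configurable because
no numeric rule is standard. Biofix is computed from whatever records are
passed in, so a per-site biofix is obtained by grouping or filtering
first; pooling all sites of an orchard type is the default analysis
posture.

Captures are partitioned into generation flights on the degree-day axis by
`generation_windows()` / `split_generations()`. Two cutoff conventions are
built in: *constrained* (the reference model's flight-completion values,
460 and 1057.5 DD — mid-ranges of the published ~455–465 and ~1055–1060 DD
intervals) and *unconstrained* (empirically observed capture shut-down,
540 and 1185 DD from ~530–550 and ~1175–1195 DD). Windows are half-open
and upper-inclusive, `(start, cutoff]`, so a capture exactly at a cutoff
belongs to the earlier flight; generation 1 additionally includes the
biofix check itself (DD = 0). Captures beyond the second cutoff are
labelled as the partial third flight and excluded from modelling. The
degree-day axis of the second generation remains DD-from-biofix, matching
how the curves are plotted in practice.

One irreconcilable feature of the published second-flight parameters is
worth documenting: they place 50% emergence near or beyond 1400–1700 DD
from biofix, past both the printed second-generation cutoffs and a
realistic Pennsylvania season's thermal budget. The package does not try
to repair this — reference rows are used as supplied — but it is the
reason the end-to-end simulation checks recover parameters on an isolated
single flight (see below).

`cumulative_percent()` converts a generation's captures to the $(X, Y)$
pairs of the model, pooling checks that share a degree-day value so $X$ is
strictly increasing, and normalizing by the generation total so the final
$Y$ is exactly 1. Cross-site averaging (`average_curves()`) interpolates
each site's curve onto a common grid and averages point-wise, giving every
site equal weight; the averaging order (per-site curves first, then the
mean) preserves site weighting and keeps the averaged curve inside
$[0, 1]$ with endpoint 1.

## Numerical choices in fitting

Two practical issues arise at the curve's ends:

* **Endpoints.** Proportions of exactly 0 or 1 have no logit. The default
  policy drops them (staying closest to "transform the proportions"); the
  alternative `"empirical"` policy shrinks every proportion to
  $\tilde p = (np + 0.5)/(n + 1)$ and keeps all checks.
* **Fitting region.** In the extreme tails a single moth moves the logit
  by a large step — at $p = 0.003$ with 1000 moths, one capture is a ~0.3
  logit jump — so tail points carry count noise rather than curve
  information, and they sit at high leverage. Fits therefore default to
  the 1–99% cumulative-capture region (`prop_window = c(0.01, 0.99)`),
  the same region over which round-trip recovery is evaluated;
  `c(0, 1)` restores keep-everything behaviour.

Degenerate inputs refuse loudly: fewer than 3 usable points, or all points
at one degree-day value, are classed errors rather than silent `NA`s.
Adjusted $R^2$ is the usual $1 - (1 - R^2)(n-1)/(n-2)$ of the logit-scale
simple regression. `dd_at_fraction()` inverts the fitted curve in closed
form, and `compare_delay()` differences two models' inversions — the
statistic used to express how much later a local population flies than the
reference at, say, 10/50/90% emergence.

## ANCOVA model comparison

`compare_flight_curves()` uses the classic two-stage analysis of
covariance on the pooled logit-scale points: slope equality is the F-test
of the group × DD interaction in the full model, and intercept equality is
the F-test of the group main effect in the parallel-slopes model. The
two-stage construction is the textbook one; the source analyses report
both p-values per comparison without stating the model structure.
P-values are reported at full precision (never rounded to "0.000"), and no
multiple-testing correction is applied across a comparison grid —
`compare_curve_grid()` instead annotates the number of comparisons made.

## Validation bands

`prediction_band()` computes the standard simple-linear-regression
mean-response and new-observation intervals *on the logit scale* and
back-transforms the endpoints with the inverse logit. The back-transform
is monotone, so the nesting `pi_low <= ci_low <= fitted <= ci_high <=
pi_high` survives and all limits stay inside $[0, 1]$; building intervals
on the proportion scale instead would break down at the boundaries.
`evaluate_fit()` scores a held-out curve by the squared correlation of
observed and predicted proportions — the proportion scale matches how
observed curves are plotted; a logit-scale $R^2$ would weight the tails
very differently — together with the fraction of observed points inside
each band.

## What the simulator emulates

`scenario_config()` / `simulate_scenario()` generate a full synthetic
monitoring campaign so every pipeline stage is testable without any field
data:

* **Temperatures.** Daily means follow an annual sinusoid (defaults:
  mean 11 °C, amplitude 13 °C, peak at day-of-year 199 — an Appalachian
  fruit-belt profile) plus stationary AR(1) noise (marginal SD 2.5 °C,
  lag-1 correlation 0.7); `tmin`/`tmax` sit half the 10 °C diurnal range
  below/above. These values give a season of roughly 1300–1500 DD above
  10 °C between mid-April and mid-October, the regime in which the
  reference cutoffs (540/1185 DD) and observed flight-end (~1525 DD) make
  sense.
* **Flights.** Each adult's emergence DD is drawn from the configured
  logistic law; defaults are centred on the published unconstrained
  commercial CM L2 rows, so the synthetic pipeline exercises the actual
  parameter regime. The first flight optionally becomes a two-mode
  mixture (weight + DD offset) to emulate the bimodal first flight seen
  in the field; females lag males by a protandry parameter (default
  60 DD, roughly the reported 7–12 day head start of males). Emergence
  drawn beyond the season's thermal budget stays unobserved under the
  default `late_emergence = "diapause"`; the `"season_end"` mode closes
  the flight record at the last check so that every adult is accounted
  for, which is what the exact self-consistency checks use.
* **Trapping.** Checks run twice weekly (3/4-day alternation). The
  configured biofix is pinned to a check date, and emergence mass at
  negative DD is folded into the biofix check — biofix *is* first
  sustained capture, so no captures precede it. Each check, every trap's
  expected catch is (emerged and uncaught) × trap efficiency for its lure
  and sex (CM L2 is male-only; CM DAC catches both sexes, females less
  efficiently), counts are drawn from the noise model, and captures
  deplete the shared uncaught pool, so captured ≤ emerged ≤ population
  holds by construction. Abandoned orchards default to a 2.5× abundance
  multiplier.
* **Noise.** `"poisson"`, `"negative_binomial"` (NB1: the dispersion
  parameter is the variance-to-mean ratio, default 1.5 — counts 50% more
  variable than Poisson, typical of overdispersed trap series), or
  `"off"` — a deterministic expectation mode that emits expected,
  possibly fractional, counts. Expectation mode exists for exactness: with
  certain capture it reproduces the generating CDF at every check DD, so
  the pipeline round-trips the generating $(\beta_0, \beta_1)$ to
  machine precision.

What the simulator does *not* emulate: trap rotation and lure aging,
mating-disruption plume effects, spatial structure among traps, and
mechanistic diapause/overwintering. Passing tests therefore demonstrate
the pipeline's internal consistency and statistical calibration under the
stated noise models, not fidelity to any particular orchard's field data.

## Known limitations

The reported standard errors are the iid-OLS ones, as in the source
analyses. Cumulative curves built from counts violate the iid assumption
twice over: successive points share all earlier captures, and the
empirical CDF of a finite cohort deviates from its generating curve in
smooth, Brownian-bridge-like excursions that the fit absorbs into the
parameters rather than the residuals. In simulation the true sampling SD
of $(\hat\beta_0, \hat\beta_1)$ is several times the reported SE. The
package keeps the conventional estimator (weighted or GLM variants are
deliberately out of scope) and treats recovery claims accordingly: the
end-to-end checks compare estimates to generating values against the
*sampling* spread across simulation replicates, and users should read the
reported SEs as describing scatter about the logit line, not full
curve-to-curve uncertainty.

Problem sizes used by the checked examples and tests — 40-point curves for
round trips, 1000-day thermal series for the accumulation oracle, 2000
null and 500 power replicates for ANCOVA calibration, 1000 replicates for
prediction-interval coverage, and 100 seeds of 1000-moth seasons for
end-to-end recovery — were chosen so each property is measured with
comfortable Monte-Carlo margin while the whole suite stays quick on a
laptop.

## A worked season

```{r worked, fig.width = 6, fig.height = 4}
cfg <- scenario_config("abandoned", seed = 2007, noise = "poisson")
sim <- simulate_scenario(cfg)
sim

curves <- build_flight_curves(sim$traps, sim$temps,
                              windows = generation_windows("unconstrained"))
fit1 <- fit_flight_model(filter(curves, lure == "CM_L2", generation == 1),
                         label = "simulated abandoned, flight 1")
glance(fit1)

compare_delay(fit1, pete_flight_model(1), q = c(0.1, 0.5, 0.9))

tidy(compare_flight_curves(
  filter(curves, lure == "CM_L2", generation == 1),
  filter(curves, lure == "CM_DAC", generation == 1),
  labels = c("CM L2", "CM DAC")
))

autoplot(prediction_band(fit1, seq(0, 1200, by = 10)))
```
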