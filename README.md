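# pcmflight

Degree-day flight-phenology models for codling moth (*Cydia pomonella*)
from pheromone-trap captures and daily temperatures.

Codling moth is the key internal fruit-feeding pest of apple, and spray
timing against it rests on predicting what fraction of the adult flight
has occurred by a given amount of thermal time. `pcmflight` implements the
full analysis chain used to re-specify such flight models locally and
compare them with the long-serving PETE reference model:

* **Thermal time** — daily degree-days by the simple-average method with
  10 °C / 31 °C thresholds and horizontal cutoff, accumulated from biofix
  (`daily_degree_days()`, `accumulate_degree_days()`).
* **Trap series** — biofix detection as the first sustained capture,
  mean seasonal capture (± SEM) per trap, generation partitioning under
  constrained/unconstrained degree-day cutoffs, cumulative-percent curves
  (`detect_biofix()`, `mean_seasonal_capture()`, `generation_windows()`,
  `build_flight_curves()`).
* **Flight model** — the logistic flight curve
  `E(Y) = e^(β₀+β₁X) / (1 + e^(β₀+β₁X))` fitted by logit-linear ordinary
  least squares, with inversion and delay statistics
  (`fit_flight_model()`, `dd_at_fraction()`, `compare_delay()`), plus the
  published PCM/PETE parameter rows as ready-made reference models
  (`cm_flight_parameters()`, `pete_flight_model()`).
* **Model comparison** — two-stage ANCOVA tests of slope and intercept
  equality between flight curves (`compare_flight_curves()`,
  `compare_curve_grid()`).
* **Validation** — 95% confidence and prediction bands computed on the
  logit scale and back-transformed, with R² and band-coverage scoring of
  held-out curves (`prediction_band()`, `evaluate_fit()`).
* **Simulation** — a trap-capture simulator (sinusoid + AR(1)
  temperatures, per-generation logistic emergence with optional bimodal
  first flight and protandry, lure/sex-specific trap efficiencies,
  Poisson/negative-binomial/deterministic count noise) so the whole
  pipeline is exercisable with no field data (`scenario_config()`,
  `simulate_scenario()`).

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects support `tidy()`, `glance()`, `predict()` and
`autoplot()`.

## Worked example

Simulate a season in an abandoned orchard, build flight curves, fit the
first flight, and compare it with the PETE reference:

```r
library(pcmflight)
library(dplyr)

sim <- simulate_scenario(scenario_config("abandoned", seed = 2007,
                                         noise = "poisson"))
sim
#> Simulated codling-moth monitoring scenario (abandoned orchard)
#>   season: 2007-04-15 to 2007-10-15 | 52 trap checks
#>   biofix: 2007-04-28 | noise: poisson
#>   total males captured: 3531 | females: 1605

curves <- build_flight_curves(sim$traps, sim$temps,
                              windows = generation_windows("unconstrained"))
fit1 <- fit_flight_model(filter(curves, lure == "CM_L2", generation == 1),
                         label = "simulated abandoned, flight 1")
glance(fit1)
#> # A tibble: 1 × 6
#>   adj.r.squared sigma n_obs df.residual dd_50 label
#>           <dbl> <dbl> <int>       <int> <dbl> <chr>
#> 1         0.987 0.164    16          14  352. simulated abandoned, flight 1

compare_delay(fit1, pete_flight_model(1), q = c(0.1, 0.5, 0.9))
#> # A tibble: 3 × 4
#>       q  dd_a  dd_b delay_dd
#>   <dbl> <dbl> <dbl>    <dbl>
#> 1   0.1  123.  110.     13.4
#> 2   0.5  352.  293.     58.5
#> 3   0.9  580.  476.    104.
```

The fitted curve explains 98.7% of the logit-scale variance on 16 trap
checks and puts 50% flight at ~352 DD from biofix; positive `delay_dd`
means the simulated local population reaches each emergence fraction
later than the PETE reference predicts (here by ~59 DD at 50% emergence —
the simulator's default emergence law is centred on the published local
parameters, which lag the reference). ANCOVA then quantifies whether two
curves share slope/intercept:

```r
tidy(compare_flight_curves(
  filter(curves, lure == "CM_L2", generation == 1),
  filter(curves, lure == "CM_DAC", generation == 1),
  labels = c("CM L2", "CM DAC")))
#> # A tibble: 2 × 6
#>   term      estimate statistic    df df.residual p.value
#>   <chr>        <dbl>     <dbl> <dbl>       <dbl>   <dbl>
#> 1 slope     0.000168    0.186      1          28   0.669
#> 2 intercept 0.0132      0.0593     1          29   0.809
```

Both lures sample the same simulated flight, so neither slope nor
intercept differs — large p-values are the right answer here. See
`vignette("flight-phenology-methods")` for the model, the simulator's
design, and the package's numerical choices.

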