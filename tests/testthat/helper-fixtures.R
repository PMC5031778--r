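# Deterministic fixtures built in code; no files.

# Noise-free cumulative-emergence curve from a logistic law, sampled across
# the 1%-99% region of the curve (the region round-trip fitting uses).
make_logistic_curve <- function(beta0, beta1, n = 40, q_range = c(0.01, 0.99)) {
  dd <- seq((qlogis(q_range[1]) - beta0) / beta1,
            (qlogis(q_range[2]) - beta0) / beta1,
            length.out = n)
  tibble::tibble(dd = dd, cum_prop = plogis(beta0 + beta1 * dd), n_total = 1e6)
}

# Curve with i.i.d. Gaussian noise added on the logit scale.
make_noisy_curve <- function(beta0, beta1, dd, sd) {
  lp <- beta0 + beta1 * dd + stats::rnorm(length(dd), 0, sd)
  tibble::tibble(dd = dd, cum_prop = plogis(lp), n_total = 1e6)
}

# Minimal constant-temperature table: each day yields the same degree-days.
make_temps <- function(start = "2007-04-15", n_days = 30, tmin = 15, tmax = 25) {
  tibble::tibble(date = as.Date(start) + seq_len(n_days) - 1,
                 tmin_c = tmin, tmax_c = tmax)
}

# Trap-record table from per-check male totals for a single trap.
make_records <- function(male_counts, start = "2007-04-20", by = 3,
                         female_counts = 0, site = "S1",
                         orchard_type = "commercial", lure = "CM_L2") {
  tibble::tibble(
    check_date = as.Date(start) + by * (seq_along(male_counts) - 1),
    site = site, orchard_type = orchard_type, lure = lure,
    trap_id = paste0(site, "_", lure, "_T1"),
    males = male_counts,
    females = rep_len(female_counts, length(male_counts))
  )
}

# Scenario used by the end-to-end recovery checks: one generation, certain
# capture, so the capture record mirrors the emergence process itself.
recovery_config <- function(seed, noise = "off") {
  scenario_config(
    "commercial",
    n_adults = c(gen1 = 1000, gen2 = 0),
    trap_efficiency = list(CM_L2 = c(male = 1, female = 0),
                           CM_DAC = c(male = 0, female = 0)),
    noise = noise,
    late_emergence = "season_end",
    seed = seed
  )
}

recovery_fit <- function(seed, noise = "off") {
  sim <- simulate_scenario(recovery_config(seed, noise))
  curves <- suppressMessages(
    build_flight_curves(sim$traps, sim$temps, windows = c(2000, 4000))
  )
  fit_flight_model(dplyr::filter(curves, lure == "CM_L2", generation == 1))
}
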