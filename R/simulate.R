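#' Scenario configuration for the trap-capture simulator
#'
#' Bundles every knob of the synthetic orchard: the season, a sinusoid-plus-
#' AR(1) daily temperature model, per-generation adult population sizes with
#' an orchard-type abundance multiplier, logistic emergence laws on the
#' degree-day-from-biofix axis (with an optional bimodal first flight and a
#' protandry lag for females), lure- and sex-specific trap efficiencies, the
#' twice-weekly check schedule, and the count noise model.
#'
#' Default emergence parameters are centred on the published unconstrained
#' commercial CM L2 flight-model values (see [cm_flight_parameters()]), so
#' the simulator exercises the parameter regime the real analysis operates
#' in. Abandoned orchards default to a 2.5x abundance multiplier, matching
#' the observation that populations run higher where no insecticide program
#' operates. Moths whose drawn emergence degree-day exceeds the season's
#' thermal budget are, under the default `late_emergence = "diapause"`,
#' never observed (biologically: they stay in diapause); with
#' `"season_end"` the flight record is instead closed out at the final
#' check, so every adult is eventually accounted for — the mode used for
#' exact end-to-end checks.
#'
#' @param orchard_type `"commercial"` or `"abandoned"`.
#' @param season_start,season_end Season limits (dates); traps are checked
#'   twice weekly between them.
#' @param temp Daily temperature model: list with `mean` and `amplitude`
#'   (degC) and `peak_doy` of the annual sinusoid of the daily mean,
#'   `ar_sd` (marginal SD, degC) and `ar_phi` of AR(1) day-to-day noise,
#'   and `diurnal_range` (degC) between `tmin` and `tmax`.
#' @param n_adults Named vector `c(gen1 = , gen2 = )`: adults per sex per
#'   site before the abundance multiplier.
#' @param abundance_multiplier Named vector over orchard types.
#' @param emergence Per-generation logistic emergence parameters on the
#'   DD-from-biofix scale; `gen1` may add `bimodal_weight` (mixture weight of
#'   the first mode; 1 disables bimodality) and `bimodal_offset_dd` (DD shift
#'   of the second mode).
#' @param protandry_dd Female emergence lag behind males, in degree-days.
#' @param trap_efficiency Per-lure, per-sex capture probability per check of
#'   an emerged, uncaught moth. `CM_L2` is a male-only lure (female
#'   efficiency 0); `CM_DAC` attracts both sexes.
#' @param check_interval_days Alternating day gaps between checks (default
#'   3, 4: twice weekly).
#' @param biofix_check Index of the check at which sustained flight begins;
#'   the biofix is pinned to a check date so that detected and configured
#'   biofix coincide.
#' @param noise `"negative_binomial"` (default, dispersion
#'   `nb_dispersion`), `"poisson"`, or `"off"` — a deterministic expectation
#'   mode emitting expected (possibly fractional) counts for exact tests.
#' @param nb_dispersion Negative-binomial dispersion, expressed as the
#'   variance-to-mean ratio of a check's count (default 1.5: trap counts
#'   50% more variable than Poisson). Must exceed 1.
#' @param late_emergence `"diapause"` or `"season_end"` (see Details).
#' @param thresholds Lower/upper degree-day thresholds.
#' @param n_sites,traps_per_lure Sampling structure.
#' @param seed RNG seed used by [simulate_scenario()]; a fixed seed makes
#'   the simulated records bit-identical.
#' @return A `scenario_config` list.
#' @examples
#' cfg <- scenario_config("commercial", seed = 42)
#' sim <- simulate_scenario(cfg)
#' head(sim$traps)
#' @export
scenario_config <- function(orchard_type = c("commercial", "abandoned"),
                            season_start = "2007-04-15",
                            season_end = "2007-10-15",
                            temp = list(),
                            n_adults = c(gen1 = 500, gen2 = 400),
                            abundance_multiplier = c(commercial = 1, abandoned = 2.5),
                            emergence = list(),
                            protandry_dd = 60,
                            trap_efficiency = list(CM_L2 = c(male = 0.4, female = 0),
                                                   CM_DAC = c(male = 0.4, female = 0.1)),
                            check_interval_days = c(3, 4),
                            biofix_check = 4,
                            noise = c("negative_binomial", "poisson", "off"),
                            nb_dispersion = 1.5,
                            late_emergence = c("diapause", "season_end"),
                            thresholds = c(lower = 10, upper = 31),
                            n_sites = 1, traps_per_lure = 2,
                            seed = NULL) {
  temp_default <- list(mean = 11, amplitude = 13, peak_doy = 199,
                       ar_sd = 2.5, ar_phi = 0.7, diurnal_range = 10)
  temp <- utils::modifyList(temp_default, temp)
  emergence_default <- list(
    gen1 = list(beta0 = -3.799, beta1 = 0.008,
                bimodal_weight = 1, bimodal_offset_dd = 250),
    gen2 = list(beta0 = -10.290, beta1 = 0.006)
  )
  emergence <- utils::modifyList(emergence_default, emergence)
  cfg <- list(
    orchard_type = match.arg(orchard_type),
    season_start = as.Date(season_start),
    season_end = as.Date(season_end),
    temp = temp,
    n_adults = n_adults,
    abundance_multiplier = abundance_multiplier,
    emergence = emergence,
    protandry_dd = protandry_dd,
    trap_efficiency = trap_efficiency,
    check_interval_days = check_interval_days,
    biofix_check = biofix_check,
    noise = match.arg(noise),
    nb_dispersion = nb_dispersion,
    late_emergence = match.arg(late_emergence),
    thresholds = thresholds,
    n_sites = n_sites,
    traps_per_lure = traps_per_lure,
    seed = seed
  )
  validate_scenario(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario <- function(cfg) {
  if (cfg$season_end <= cfg$season_start + 14) {
    abort("Degenerate season: `season_end` must be well after `season_start`.")
  }
  if (any(cfg$n_adults < 0)) abort("`n_adults` must be non-negative.")
  w <- cfg$emergence$gen1$bimodal_weight
  if (w < 0 || w > 1) abort("`bimodal_weight` must lie in [0, 1].")
  for (g in c("gen1", "gen2")) {
    if (cfg$emergence[[g]]$beta1 <= 0) abort("Emergence `beta1` must be positive.")
  }
  effs <- unlist(cfg$trap_efficiency)
  if (any(effs < 0 | effs > 1)) abort("Trap efficiencies must lie in [0, 1].")
  if (cfg$temp$ar_sd < 0 || cfg$temp$diurnal_range <= 0) {
    abort("Temperature noise SD must be >= 0 and diurnal range > 0.")
  }
  if (cfg$noise == "negative_binomial" && cfg$nb_dispersion <= 1) {
    abort("`nb_dispersion` is a variance-to-mean ratio and must exceed 1.")
  }
  invisible(cfg)
}

#' Trap-check schedule of a scenario
#'
#' @param config A `scenario_config`.
#' @return Vector of check dates (twice-weekly from three days after season
#'   start).
#' @export
check_schedule <- function(config) {
  gaps <- rep_len(config$check_interval_days,
                  ceiling(as.numeric(config$season_end - config$season_start)))
  dates <- config$season_start + cumsum(c(3, gaps))
  dates[dates <= config$season_end]
}

#' Simulate daily minimum/maximum temperatures
#'
#' Daily mean temperature follows an annual sinusoid plus stationary AR(1)
#' noise; `tmin`/`tmax` sit half the diurnal range below/above the daily
#' mean, so `tmin <= tmax` always holds. With `ar_sd = 0` the series is an
#' exact deterministic sinusoid.
#'
#' @param config A `scenario_config`.
#' @param seed Optional seed for this call only.
#' @return Tibble `date`, `tmin_c`, `tmax_c` covering the season.
#' @export
simulate_temperatures <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- config$temp
  dates <- seq(config$season_start, config$season_end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  mid <- tm$mean + tm$amplitude * cos(2 * pi * (doy - tm$peak_doy) / 365)
  n <- length(dates)
  if (tm$ar_sd > 0) {
    eps <- numeric(n)
    eps[1] <- stats::rnorm(1, 0, tm$ar_sd)
    innov_sd <- tm$ar_sd * sqrt(1 - tm$ar_phi^2)
    for (i in seq_len(n - 1)) {
      eps[i + 1] <- tm$ar_phi * eps[i] + stats::rnorm(1, 0, innov_sd)
    }
    mid <- mid + eps
  }
  tibble(
    date = dates,
    tmin_c = mid - tm$diurnal_range / 2,
    tmax_c = mid + tm$diurnal_range / 2
  )
}

# Emergence CDF for one sex on the DD-from-biofix axis (mixture-logistic for
# the optionally bimodal first flight; females lag by the protandry DD).
emergence_cdf <- function(config, generation, sex) {
  par <- config$emergence[[paste0("gen", generation)]]
  lag <- if (sex == "female") config$protandry_dd else 0
  w <- if (generation == 1) par$bimodal_weight else 1
  off <- if (generation == 1) par$bimodal_offset_dd else 0
  function(x) {
    x <- x - lag
    w * plogis(par$beta0 + par$beta1 * x) +
      (1 - w) * plogis(par$beta0 + par$beta1 * (x - off))
  }
}

# Draw emergence DDs for n moths (stochastic modes).
draw_emergence <- function(n, config, generation, sex) {
  par <- config$emergence[[paste0("gen", generation)]]
  lag <- if (sex == "female") config$protandry_dd else 0
  loc <- -par$beta0 / par$beta1
  sc <- 1 / par$beta1
  x <- stats::rlogis(n, location = loc, scale = sc)
  if (generation == 1 && par$bimodal_weight < 1) {
    second <- stats::runif(n) >= par$bimodal_weight
    x[second] <- x[second] + par$bimodal_offset_dd
  }
  x + lag
}

#' Simulate sexed, per-lure trap-capture records
#'
#' Converts the daily temperatures to degree-days from the configured biofix
#' (a trap-check date), draws each adult's emergence degree-day from the
#' configured (mixture-)logistic law — females lagged by the protandry
#' degree-days — and walks the check schedule: at each check every trap's
#' expected catch is (emerged and not yet caught) x trap efficiency for its
#' lure and sex, counts are drawn from the configured noise model, and
#' captures deplete the uncaught pool, so total captured never exceeds total
#' emerged. Emergence mass at negative degree-days (before sustained flight)
#' is folded into the biofix check. With `noise = "off"` no individual draws
#' are made and expected (possibly fractional) counts are emitted.
#'
#' @param config A `scenario_config`.
#' @param temps Daily temperatures covering the season (e.g. from
#'   [simulate_temperatures()]).
#' @param seed Optional seed for this call only.
#' @return Trap-record tibble: `check_date`, `site`, `orchard_type`, `lure`,
#'   `trap_id`, `males`, `females`, with attributes `biofix_date` and
#'   `check_dd` (degree-days from biofix at each check).
#' @export
simulate_captures <- function(config, temps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  checks <- check_schedule(config)
  biofix_date <- checks[config$biofix_check]
  dd <- accumulate_degree_days(temps, anchor = biofix_date,
                               lower = config$thresholds[["lower"]],
                               upper = config$thresholds[["upper"]])
  x_check <- dd$cumulative_dd[match(checks, dd$date)]
  x_check[is.na(x_check)] <- -Inf  # pre-biofix checks see no flight
  x_end <- max(dd$cumulative_dd)
  mult <- config$abundance_multiplier[[config$orchard_type]]
  n_checks <- length(checks)

  records <- list()
  for (site in paste0("S", seq_len(config$n_sites))) {
    # per-sex cumulative emerged counts at each check, pooled over generations
    emerged <- list()
    for (sex in c("male", "female")) {
      total <- 0
      cum <- numeric(n_checks)
      for (g in 1:2) {
        n_g <- round(config$n_adults[[paste0("gen", g)]] * mult)
        if (n_g == 0) next
        total <- total + n_g
        if (config$noise == "off") {
          cdf <- emergence_cdf(config, g, sex)
          e <- n_g * cdf(pmax(x_check, -Inf))
          e[x_check == -Inf] <- 0
          if (config$late_emergence == "season_end") e[n_checks] <- n_g
          cum <- cum + e
        } else {
          xe <- draw_emergence(n_g, config, g, sex)
          xe <- pmax(xe, 0)  # pre-biofix emergence folded into the biofix check
          if (config$late_emergence == "season_end") {
            xe <- pmin(xe, x_end)
          } else {
            xe <- xe[xe <= x_end]  # unemerged by season end: stays in diapause
          }
          cum <- cum + vapply(x_check, function(x) sum(xe <= x), numeric(1))
        }
      }
      emerged[[sex]] <- list(cum = cummax(cum), total = total)
    }
    for (lure in names(config$trap_efficiency)) {
      counts <- list(male = NULL, female = NULL)
      for (sex in c("male", "female")) {
        eff <- config$trap_efficiency[[lure]][[sex]]
        cnt <- matrix(0, nrow = config$traps_per_lure, ncol = n_checks)
        if (eff > 0 && emerged[[sex]]$total > 0) {
          captured <- 0
          for (i in seq_len(n_checks)) {
            if (x_check[i] == -Inf) next
            for (tr in seq_len(config$traps_per_lure)) {
              avail <- emerged[[sex]]$cum[i] - captured
              mu <- avail * eff
              ct <- switch(config$noise,
                off = mu,
                poisson = stats::rpois(1, mu),
                # NB1 parameterization: Var = dispersion * mu (dispersion is
                # the variance-to-mean ratio, > 1), i.e. size = mu/(disp - 1)
                negative_binomial = if (mu <= 0) 0 else {
                  stats::rnbinom(1, size = mu / (config$nb_dispersion - 1),
                                 mu = mu)
                }
              )
              ct <- min(ct, avail)
              captured <- captured + ct
              cnt[tr, i] <- ct
            }
          }
        }
        counts[[sex]] <- cnt
      }
      for (tr in seq_len(config$traps_per_lure)) {
        records[[length(records) + 1]] <- tibble(
          check_date = checks,
          site = site,
          orchard_type = config$orchard_type,
          lure = lure,
          trap_id = paste(site, lure, paste0("T", tr), sep = "_"),
          males = counts$male[tr, ],
          females = counts$female[tr, ]
        )
      }
    }
  }
  out <- bind_rows(records) |> arrange(.data$check_date, .data$site,
                                       .data$lure, .data$trap_id)
  attr(out, "biofix_date") <- biofix_date
  attr(out, "check_dd") <- setNames(x_check, format(checks))
  out
}

#' Simulate a complete monitoring scenario
#'
#' Seeds the RNG from `config$seed` (when set) and generates the season's
#' temperatures and trap records in one reproducible stream: the same seed
#' always yields identical output.
#'
#' @param config A `scenario_config`.
#' @return List of class `cm_scenario`: `temps`, `traps`, `biofix_date`,
#'   `check_dates`, `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  temps <- simulate_temperatures(config)
  traps <- simulate_captures(config, temps)
  structure(
    list(
      temps = temps,
      traps = traps,
      biofix_date = attr(traps, "biofix_date"),
      check_dates = check_schedule(config),
      config = config
    ),
    class = "cm_scenario"
  )
}

#' @export
print.cm_scenario <- function(x, ...) {
  cat("Simulated codling-moth monitoring scenario (", x$config$orchard_type,
      " orchard)\n", sep = "")
  cat("  season:", format(x$config$season_start), "to",
      format(x$config$season_end), "|", length(x$check_dates), "trap checks\n")
  cat("  biofix:", format(x$biofix_date), "| noise:", x$config$noise, "\n")
  cat("  total males captured:", round(sum(x$traps$males), 1),
      "| females:", round(sum(x$traps$females), 1), "\n")
  invisible(x)
}
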