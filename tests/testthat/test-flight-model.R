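test_that("logit and inverse logit honour their contracts", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.9), log(9))
  expect_error(logit(1), class = "pcm_domain_error")
  expect_error(logit(0), class = "pcm_domain_error")
  expect_equal(inv_logit(0), 0.5)
  expect_equal(inv_logit(logit(0.73)), 0.73)
  expect_equal(inv_logit(1e6), 1)                  # saturates without overflow
  expect_equal(inv_logit(-1e6), 0)
})

test_that("noise-free logistic curves are recovered exactly by logit-linear fitting", {
  # round trips through several published parameter regimes
  pars <- list(c(-3.517, 0.012), c(-3.799, 0.008), c(-11.391, 0.008),
               c(-9.303, 0.006))
  for (p in pars) {
    fit <- fit_flight_model(make_logistic_curve(p[1], p[2]))
    expect_equal(fit$beta0, p[1], tolerance = 1e-9)
    expect_equal(fit$beta1, p[2], tolerance = 1e-9)
    expect_true(fit$adj_r2 > 1 - 1e-10)
  }
})

test_that("fit refuses degenerate designs and too-few points", {
  expect_error(
    fit_flight_model(tibble::tibble(dd = c(1, 2), cum_prop = c(0.2, 0.4))),
    class = "pcm_insufficient_data"
  )
  expect_error(
    fit_flight_model(tibble::tibble(dd = rep(5, 4),
                                    cum_prop = c(0.2, 0.3, 0.4, 0.5))),
    class = "pcm_degenerate_design"
  )
  # all-informative-point curve of 3 collinear logits: perfect fit
  fit3 <- fit_flight_model(make_logistic_curve(-4, 0.01, n = 3))
  expect_equal(fit3$adj_r2, 1)
})

test_that("endpoint policies handle proportions of 0 and 1", {
  curve <- tibble::tibble(dd = c(0, 100, 200, 300, 400),
                          cum_prop = c(0, 0.3, 0.6, 0.9, 1),
                          n_total = 50)
  fit_drop <- fit_flight_model(curve, endpoint_policy = "drop")
  expect_equal(fit_drop$n_obs, 3L)
  fit_emp <- fit_flight_model(curve, endpoint_policy = "empirical",
                              prop_window = c(0, 1))
  expect_equal(fit_emp$n_obs, 5L)                  # shrunken endpoints retained
  expect_error(
    fit_flight_model(dplyr::select(curve, -n_total),
                     endpoint_policy = "empirical"),
    "n_total"
  )
})

test_that("prediction, inversion and delay statistics are mutually consistent", {
  pete1 <- flight_model(-3.517, 0.012, label = "PETE gen 1")
  expect_equal(predict(pete1, dd_at_fraction(pete1, 0.5)), 0.5)
  expect_equal(dd_at_fraction(pete1, 0.5), 3.517 / 0.012, tolerance = 1e-12)
  expect_equal(predict(pete1, 293.08), 0.5, tolerance = 1e-4)
  expect_equal(predict(flight_model(0, 0.01), 0), 0.5)

  set.seed(77)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  for (i in 1:25) {
    fit <- flight_model(runif(1, -12, -2), runif(1, 0.004, 0.02))
    # round-trip identity
    expect_equal(predict(fit, dd_at_fraction(fit, qs)), qs, tolerance = 1e-12)
    # monotonicity in q
    expect_true(all(diff(dd_at_fraction(fit, qs)) > 0))
    # antisymmetry of the delay statistic
    other <- flight_model(runif(1, -12, -2), runif(1, 0.004, 0.02))
    d_ab <- compare_delay(fit, other, qs)$delay_dd
    d_ba <- compare_delay(other, fit, qs)$delay_dd
    expect_equal(d_ab, -d_ba)
  }
  expect_equal(compare_delay(pete1, pete1)$delay_dd, rep(0, 3))
  expect_error(dd_at_fraction(pete1, 1), class = "pcm_domain_error")
})

test_that("estimator bias shrinks as curves get denser and counts grow", {
  # binomial capture noise at two study sizes; logit-OLS bias should shrink
  beta0 <- -3.8; beta1 <- 0.008
  run <- function(n_moths, n_checks, reps) {
    set.seed(505)
    est <- replicate(reps, {
      dd <- seq(30, 1000, length.out = n_checks)
      counts <- rbinom(n_checks, n_moths, plogis(beta0 + beta1 * dd))
      curve <- tibble::tibble(dd = dd, cum_prop = counts / n_moths,
                              n_total = n_moths)
      coef(fit_flight_model(curve))
    })
    rowMeans(est) - c(beta0, beta1)
  }
  small <- run(60, 8, 60)
  large <- run(4000, 40, 60)
  expect_true(abs(large[1]) < abs(small[1]))
  expect_true(abs(large[2]) <= abs(small[2]) + 1e-5)
  expect_true(all(abs(large) < c(0.05, 1e-4)))
})

test_that("tidy and glance return one row per term / per model", {
  fit <- fit_flight_model(make_logistic_curve(-3.8, 0.008))
  td <- tidy(fit)
  expect_equal(td$term, c("beta0", "beta1"))
  expect_true(all(c("estimate", "std.error", "statistic", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_obs, fit$n_obs)
  expect_equal(gl$dd_50, dd_at_fraction(fit, 0.5))
})

test_that("reference parameter table wraps into usable flight models", {
  tab <- cm_flight_parameters()
  expect_equal(nrow(tab), 24)
  expect_true(all(tab$beta1 > 0))
  pete2 <- pete_flight_model(2)
  expect_equal(coef(pete2), c(beta0 = -11.391, beta1 = 0.008))
  pcm <- reference_flight_model("unconstrained", 1, "CM_L2", "commercial")
  expect_equal(coef(pcm), c(beta0 = -3.799, beta1 = 0.008))
  expect_error(reference_flight_model("constrained", 1, "CM_L2"), "unique")
})
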