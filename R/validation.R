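#' Confidence and prediction bands for a fitted flight curve
#'
#' Computes the fitted flight curve with 95% confidence limits (for the mean
#' response) and prediction limits (for a new observation) over a
#' degree-day grid. Intervals are the standard simple-linear-regression
#' intervals computed on the logit scale and back-transformed with
#' [inv_logit()]; the back-transform is monotone, so the nesting
#' `pi_low <= ci_low <= fitted <= ci_high <= pi_high` is preserved and all
#' limits stay inside \[0, 1\]. (Building the intervals directly on the
#' proportion scale would break down at the curve's boundaries.)
#'
#' @param fit A `flight_fit` produced by [fit_flight_model()] (supplied
#'   reference models carry no design information and cannot produce bands).
#' @param x_grid Degree-days from biofix at which to evaluate the band.
#' @param level Nominal coverage (default 0.95).
#' @return A tibble of class `prediction_band` with columns `dd`, `fitted`,
#'   `ci_low`, `ci_high`, `pi_low`, `pi_high`; attribute `level` records the
#'   nominal coverage and attribute `scale` documents that intervals were
#'   formed on the logit scale.
#' @export
prediction_band <- function(fit, x_grid, level = 0.95) {
  stopifnot(inherits(fit, "flight_fit"))
  if (is.na(fit$df_residual) || is.na(fit$s_xx)) {
    abort("`fit` carries no regression design information (was it fitted from data?).",
          class = "pcm_insufficient_data")
  }
  if (fit$n_obs < 3) {
    abort("Bands need a fit with at least 3 observations.",
          class = "pcm_insufficient_data")
  }
  sigma <- sqrt(fit$residual_variance)
  lp <- fit$beta0 + fit$beta1 * x_grid
  leverage <- 1 / fit$n_obs + (x_grid - fit$x_bar)^2 / fit$s_xx
  se_mean <- sigma * sqrt(leverage)
  se_new <- sigma * sqrt(1 + leverage)
  tq <- qt((1 + level) / 2, df = fit$df_residual)
  out <- tibble(
    dd = x_grid,
    fitted = plogis(lp),
    ci_low = plogis(lp - tq * se_mean),
    ci_high = plogis(lp + tq * se_mean),
    pi_low = plogis(lp - tq * se_new),
    pi_high = plogis(lp + tq * se_new)
  )
  attr(out, "level") <- level
  attr(out, "scale") <- "logit (back-transformed)"
  attr(out, "label") <- fit$label
  class(out) <- c("prediction_band", class(out))
  out
}

#' Evaluate a flight model against an observed cumulative curve
#'
#' Held-out validation of a fitted flight curve: the coefficient of
#' agreement between observed and predicted cumulative proportions (squared
#' Pearson correlation, computed on the proportion scale to match how
#' observed curves are plotted) and the fraction of observed points falling
#' inside the confidence and prediction bands at the observed degree-days.
#'
#' @param fit A `flight_fit` with design information.
#' @param observed Observed curve: columns `dd`, `cum_prop`, at least 2 rows.
#' @param level Band coverage used for the coverage fractions.
#' @return One-row tibble: `r2`, `coverage_ci`, `coverage_pi`, `n_points`.
#' @export
evaluate_fit <- function(fit, observed, level = 0.95) {
  observed <- as_tibble(observed)
  if (!all(c("dd", "cum_prop") %in% names(observed)) || nrow(observed) < 2) {
    abort("`observed` needs columns `dd`, `cum_prop` and at least 2 points.",
          class = "pcm_insufficient_data")
  }
  pred <- predict(fit, observed$dd)
  r2 <- suppressWarnings(stats::cor(observed$cum_prop, pred)^2)
  band <- prediction_band(fit, observed$dd, level = level)
  tibble(
    r2 = r2,
    coverage_ci = mean(observed$cum_prop >= band$ci_low &
                         observed$cum_prop <= band$ci_high),
    coverage_pi = mean(observed$cum_prop >= band$pi_low &
                         observed$cum_prop <= band$pi_high),
    n_points = nrow(observed)
  )
}
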