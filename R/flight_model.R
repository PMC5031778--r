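#' Logit and inverse-logit transforms
#'
#' The logistic flight model
#' \deqn{E(Y) = e^{\beta_0 + \beta_1 X} / (1 + e^{\beta_0 + \beta_1 X})}
#' is linearized by the logit transform \eqn{p' = \log_e[p / (1 - p)]}, so its
#' parameters can be estimated by ordinary least squares of \eqn{p'} on the
#' cumulative degree-days \eqn{X}.
#'
#' `logit()` requires `p` strictly inside (0, 1); proportions of exactly 0 or
#' 1 are handled upstream by the endpoint policy of [fit_flight_model()].
#' `inv_logit()` accepts any real value and saturates at 0/1 without
#' overflow.
#'
#' @param p Proportions in (0, 1).
#' @param x Real values on the logit scale.
#' @return Numeric vector.
#' @examples
#' logit(0.5)       # 0
#' inv_logit(0)     # 0.5
#' inv_logit(logit(0.73))
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    abort("`logit()` requires proportions strictly between 0 and 1.",
          class = "pcm_domain_error")
  }
  qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) plogis(x)

#' Construct a flight model from supplied parameters
#'
#' Wraps known logistic parameters (for example a published PETE reference
#' row) as a `flight_fit` object so it can be predicted from and compared
#' like a fitted model. Supplied models carry no regression design
#' information, so confidence/prediction bands are unavailable for them.
#'
#' @param beta0,beta1 Logit-scale intercept and slope (per degC-day from
#'   biofix).
#' @param se_beta0,se_beta1 Optional standard errors.
#' @param adj_r2,n_obs,residual_variance Optional fit diagnostics.
#' @param label Optional model label.
#' @return A `flight_fit` object.
#' @examples
#' pete1 <- flight_model(-3.517, 0.012, label = "PETE gen 1")
#' predict(pete1, dd = 293.08)
#' @export
flight_model <- function(beta0, beta1, se_beta0 = NA_real_, se_beta1 = NA_real_,
                         adj_r2 = NA_real_, n_obs = NA_integer_,
                         residual_variance = NA_real_, label = NULL) {
  new_flight_fit(
    beta0 = beta0, beta1 = beta1, se_beta0 = se_beta0, se_beta1 = se_beta1,
    adj_r2 = adj_r2, n_obs = n_obs, residual_variance = residual_variance,
    df_residual = NA_real_, x_bar = NA_real_, s_xx = NA_real_,
    label = label, source = "supplied", data = NULL
  )
}

new_flight_fit <- function(beta0, beta1, se_beta0, se_beta1, adj_r2, n_obs,
                           residual_variance, df_residual, x_bar, s_xx,
                           label, source, data) {
  if (!is.na(beta1) && beta1 <= 0) {
    warn("`beta1` <= 0: not an emergence curve (flight proportion should rise with degree-days).")
  }
  structure(
    list(
      beta0 = unname(beta0), beta1 = unname(beta1),
      se_beta0 = unname(se_beta0), se_beta1 = unname(se_beta1),
      adj_r2 = adj_r2, n_obs = n_obs,
      residual_variance = residual_variance, df_residual = df_residual,
      x_bar = x_bar, s_xx = s_xx,
      label = label %||% "flight model", source = source, data = data
    ),
    class = "flight_fit"
  )
}

#' Fit the logistic flight model by logit-linear regression
#'
#' Transforms a cumulative-percent capture curve to logits and fits an
#' unweighted ordinary least squares regression of logit on degree-days; the
#' intercept and slope are the \eqn{\beta_0}, \eqn{\beta_1} of the logistic
#' flight model. Because the logit linearization is an exact inverse of the
#' logistic, noise-free logistic data are recovered to machine precision.
#'
#' Cumulative proportions of exactly 0 or 1 (the curve always ends at 1) have
#' no logit. The `endpoint_policy` decides their fate: `"drop"` (default)
#' excludes them; `"empirical"` shrinks every proportion to
#' \eqn{\tilde p = (n p + 0.5) / (n + 1)} using the generation total
#' `n_total`, keeping all checks in the fit.
#'
#' @param curve Data frame with columns `dd` (cumulative degree-days from
#'   biofix) and `cum_prop` (cumulative proportion captured); `n_total` is
#'   required for the `"empirical"` policy. Typically one row-group of
#'   [build_flight_curves()].
#' @param endpoint_policy `"drop"` or `"empirical"`.
#' @param prop_window Cumulative-capture region retained for fitting
#'   (default 1%-99%). Outside this region a single moth moves the logit by
#'   a large step, so the extreme tails are dominated by count noise rather
#'   than by the flight curve; the default matches the region over which
#'   round-trip parameter recovery is evaluated. Use `c(0, 1)` to keep every
#'   point with a finite logit.
#' @param label Optional model label carried into printouts and comparisons.
#' @return A `flight_fit` object with components `beta0`, `beta1`,
#'   `se_beta0`, `se_beta1`, `adj_r2`, `n_obs`, `residual_variance`, and the
#'   design summaries needed for prediction bands. Supports [coef()],
#'   [predict()], [tidy()], [glance()] and [autoplot()].
#' @examples
#' dd <- seq(100, 900, by = 40)
#' curve <- tibble::tibble(dd = dd, cum_prop = inv_logit(-3.8 + 0.008 * dd))
#' fit_flight_model(curve)
#' @export
fit_flight_model <- function(curve, endpoint_policy = c("drop", "empirical"),
                             prop_window = c(0.01, 0.99), label = NULL) {
  endpoint_policy <- match.arg(endpoint_policy)
  pts <- logit_points(curve, endpoint_policy, prop_window)
  if (nrow(pts) < 3) {
    abort(paste0("Need at least 3 usable points with proportions in (0, 1); got ",
                 nrow(pts), "."),
          class = "pcm_insufficient_data")
  }
  if (var(pts$dd) == 0) {
    abort("All points share one degree-day value; slope is not estimable.",
          class = "pcm_degenerate_design")
  }
  fit <- lm(lp ~ dd, data = pts)
  # noise-free curves fit exactly; summary.lm's perfect-fit warning is expected
  s <- suppressWarnings(summary(fit))
  cf <- s$coefficients
  new_flight_fit(
    beta0 = cf["(Intercept)", "Estimate"],
    beta1 = cf["dd", "Estimate"],
    se_beta0 = cf["(Intercept)", "Std. Error"],
    se_beta1 = cf["dd", "Std. Error"],
    adj_r2 = s$adj.r.squared,
    n_obs = nrow(pts),
    residual_variance = s$sigma^2,
    df_residual = fit$df.residual,
    x_bar = mean(pts$dd),
    s_xx = sum((pts$dd - mean(pts$dd))^2),
    label = label, source = paste0("fitted (endpoint policy: ", endpoint_policy, ")"),
    data = pts
  )
}

# Logit-scale points for fitting/comparison, after the endpoint policy and
# the cumulative-proportion fitting window.
logit_points <- function(curve, endpoint_policy, prop_window = c(0.01, 0.99)) {
  curve <- as_tibble(curve)
  if (!all(c("dd", "cum_prop") %in% names(curve))) {
    abort("`curve` must have columns `dd` and `cum_prop`.")
  }
  p <- curve$cum_prop
  if (endpoint_policy == "empirical") {
    if (!"n_total" %in% names(curve)) {
      abort("The \"empirical\" endpoint policy needs the `n_total` column.")
    }
    p <- (curve$n_total * p + 0.5) / (curve$n_total + 1)
  }
  keep <- p > 0 & p < 1 & p >= prop_window[1] & p <= prop_window[2]
  tibble(dd = curve$dd[keep], lp = qlogis(p[keep]))
}

#' @export
coef.flight_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' Predict cumulative emergence from a flight model
#'
#' Evaluates the logistic flight curve \eqn{E(Y) = \mathrm{inv\_logit}(\beta_0
#' + \beta_1 \cdot dd)}.
#'
#' @param object A `flight_fit`.
#' @param dd Degree-days from biofix.
#' @param ... Unused.
#' @return Proportions in (0, 1).
#' @export
predict.flight_fit <- function(object, dd, ...) {
  plogis(object$beta0 + object$beta1 * dd)
}

#' @export
print.flight_fit <- function(x, ...) {
  cat("Logistic flight model:", x$label, "\n")
  cat(sprintf("  beta0 = %.4f (SE %.4g), beta1 = %.6f (SE %.4g) per DD\n",
              x$beta0, x$se_beta0, x$beta1, x$se_beta1))
  if (!is.na(x$adj_r2)) {
    cat(sprintf("  adj. R^2 = %.3f on %d logit-scale points [%s]\n",
                x$adj_r2, x$n_obs, x$source))
  }
  cat(sprintf("  50%% emergence at %.1f DD from biofix\n",
              dd_at_fraction(x, 0.5)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flight_fit <- function(x, ...) {
  est <- c(x$beta0, x$beta1)
  se <- c(x$se_beta0, x$se_beta1)
  stat <- est / se
  p <- if (!is.na(x$df_residual)) 2 * stats::pt(abs(stat), x$df_residual, lower.tail = FALSE)
       else rep(NA_real_, 2)
  tibble(
    term = c("beta0", "beta1"),
    estimate = est, std.error = se, statistic = stat, p.value = p
  )
}

#' @exportS3Method generics::glance
glance.flight_fit <- function(x, ...) {
  tibble(
    adj.r.squared = x$adj_r2,
    sigma = sqrt(x$residual_variance),
    n_obs = x$n_obs,
    df.residual = x$df_residual,
    dd_50 = dd_at_fraction(x, 0.5),
    label = x$label
  )
}

#' Degree-days at a given cumulative-emergence fraction
#'
#' Inverts the flight curve: the degree-days from biofix at which a fraction
#' `q` of the generation's flight is complete, \eqn{(\mathrm{logit}(q) -
#' \beta_0) / \beta_1}. Satisfies `predict(fit, dd_at_fraction(fit, q)) == q`.
#'
#' @param fit A `flight_fit`.
#' @param q Fractions strictly in (0, 1); vectorized.
#' @return Degree-days from biofix.
#' @examples
#' pete1 <- flight_model(-3.517, 0.012)
#' dd_at_fraction(pete1, 0.5)  # 293.08 DD
#' @export
dd_at_fraction <- function(fit, q) {
  stopifnot(inherits(fit, "flight_fit"))
  if (any(q <= 0 | q >= 1)) {
    abort("`q` must lie strictly between 0 and 1.", class = "pcm_domain_error")
  }
  if (is.na(fit$beta1) || fit$beta1 == 0) {
    abort("`beta1` is zero; the curve cannot be inverted.",
          class = "pcm_degenerate_design")
  }
  (qlogis(q) - fit$beta0) / fit$beta1
}

#' Emergence delay between two flight models
#'
#' Difference in degree-days needed to reach the same cumulative-emergence
#' fraction under two models: positive values mean `fit_a` reaches the
#' fraction later (delayed emergence) than `fit_b`. This is the statistic
#' used to quantify how much later orchard populations fly than the PETE
#' reference predicts.
#'
#' @param fit_a,fit_b `flight_fit` objects.
#' @param q Emergence fractions at which to compare (default 10, 50, 90%).
#' @return Tibble with columns `q`, `dd_a`, `dd_b`, `delay_dd`.
#' @examples
#' pcm <- flight_model(-3.799, 0.008, label = "PCM commercial")
#' pete <- flight_model(-3.517, 0.012, label = "PETE")
#' compare_delay(pcm, pete)
#' @export
compare_delay <- function(fit_a, fit_b, q = c(0.1, 0.5, 0.9)) {
  dd_a <- dd_at_fraction(fit_a, q)
  dd_b <- dd_at_fraction(fit_b, q)
  tibble(q = q, dd_a = dd_a, dd_b = dd_b, delay_dd = dd_a - dd_b)
}
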