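#' ANCOVA comparison of two flight curves
#'
#' Tests whether two cumulative-emergence curves share a slope and an
#' intercept on the logit scale, the classic two-stage analysis of
#' covariance used to compare flight models:
#'
#' 1. **Slope equality** — F-test of the group-by-degree-day interaction in
#'    the full model `logit ~ dd * group`.
#' 2. **Intercept equality** — F-test of the group main effect in the
#'    parallel-slopes model `logit ~ dd + group`.
#'
#' Both tests are partial F-tests from nested linear models (equivalently
#' squared t-tests for single coefficients). P-values are reported at full
#' precision and no multiple-testing correction is applied across a grid of
#' comparisons; when batches of comparisons are run the caller should note
#' their number.
#'
#' @param curve_a,curve_b Cumulative curves (columns `dd`, `cum_prop`, and
#'   `n_total` for the `"empirical"` policy), each yielding at least 3
#'   usable logit points.
#' @param endpoint_policy,prop_window Endpoint handling and cumulative-
#'   capture fitting region, as in [fit_flight_model()].
#' @param labels Length-2 character labels for the two curves.
#' @return A `flight_ancova` object with components `f_slope`, `p_slope`,
#'   `f_intercept`, `p_intercept`, their degrees of freedom, the estimated
#'   slope and intercept differences (`b` minus `a`), and the group sizes.
#'   Supports [tidy()] and [glance()].
#' @examples
#' dd <- seq(50, 900, by = 50)
#' a <- tibble::tibble(dd = dd, cum_prop = inv_logit(-3.8 + 0.008 * dd))
#' b <- tibble::tibble(dd = dd, cum_prop = inv_logit(-3.5 + 0.012 * dd))
#' tidy(compare_flight_curves(a, b, labels = c("PCM", "PETE")))
#' @export
compare_flight_curves <- function(curve_a, curve_b,
                                  endpoint_policy = c("drop", "empirical"),
                                  prop_window = c(0.01, 0.99),
                                  labels = c("a", "b")) {
  endpoint_policy <- match.arg(endpoint_policy)
  pts_a <- logit_points(curve_a, endpoint_policy, prop_window)
  pts_b <- logit_points(curve_b, endpoint_policy, prop_window)
  if (nrow(pts_a) < 3 || nrow(pts_b) < 3) {
    abort("Each curve needs at least 3 usable points with proportions in (0, 1).",
          class = "pcm_insufficient_data")
  }
  dat <- bind_rows(
    mutate(pts_a, group = factor(labels[1], levels = labels)),
    mutate(pts_b, group = factor(labels[2], levels = labels))
  )
  m_common <- lm(lp ~ dd, data = dat)
  m_parallel <- lm(lp ~ dd + group, data = dat)
  m_full <- lm(lp ~ dd * group, data = dat)

  a_slope <- anova(m_parallel, m_full)
  a_int <- anova(m_common, m_parallel)

  structure(
    list(
      labels = labels,
      n = c(nrow(pts_a), nrow(pts_b)),
      slope_diff = unname(coef(m_full)[4]),
      intercept_diff = unname(coef(m_parallel)[3]),
      f_slope = a_slope$F[2],
      df_slope = c(a_slope$Df[2], a_slope$Res.Df[2]),
      p_slope = a_slope$`Pr(>F)`[2],
      f_intercept = a_int$F[2],
      df_intercept = c(a_int$Df[2], a_int$Res.Df[2]),
      p_intercept = a_int$`Pr(>F)`[2],
      endpoint_policy = endpoint_policy
    ),
    class = "flight_ancova"
  )
}

#' @export
print.flight_ancova <- function(x, ...) {
  cat("ANCOVA comparison of flight curves:", x$labels[1], "vs", x$labels[2], "\n")
  cat(sprintf("  slope:     F(%d, %d) = %.3f, p = %.4g (difference %.5g per DD)\n",
              x$df_slope[1], x$df_slope[2], x$f_slope, x$p_slope, x$slope_diff))
  cat(sprintf("  intercept: F(%d, %d) = %.3f, p = %.4g (difference %.4g, parallel slopes)\n",
              x$df_intercept[1], x$df_intercept[2], x$f_intercept,
              x$p_intercept, x$intercept_diff))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.flight_ancova <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope_diff, x$intercept_diff),
    statistic = c(x$f_slope, x$f_intercept),
    df = c(x$df_slope[1], x$df_intercept[1]),
    df.residual = c(x$df_slope[2], x$df_intercept[2]),
    p.value = c(x$p_slope, x$p_intercept)
  )
}

#' @exportS3Method generics::glance
glance.flight_ancova <- function(x, ...) {
  tibble(
    p.slope = x$p_slope, p.intercept = x$p_intercept,
    n_a = x$n[1], n_b = x$n[2],
    label_a = x$labels[1], label_b = x$labels[2]
  )
}

#' Batch ANCOVA comparisons over a grid of curve pairs
#'
#' Runs [compare_flight_curves()] for every requested pair of strata in a
#' curve table (e.g. the output of [build_flight_curves()]), returning one
#' tidy row per comparison and generation. The returned tibble carries the
#' number of comparisons as attribute `"n_comparisons"`; p-values are not
#' adjusted.
#'
#' @param curves Curve table with stratifying columns plus `generation`,
#'   `dd`, `cum_prop`, `n_total`.
#' @param pairs Data frame with columns `a` and `b` naming strata; strata
#'   are identified by pasting the `by` columns with a space.
#' @param by Stratifying columns identifying a curve.
#' @inheritParams compare_flight_curves
#' @return Tibble: `a`, `b`, `generation`, `term`, `estimate`, `statistic`,
#'   `df`, `df.residual`, `p.value`.
#' @export
compare_curve_grid <- function(curves, pairs, by = c("orchard_type", "lure"),
                               endpoint_policy = c("drop", "empirical")) {
  endpoint_policy <- match.arg(endpoint_policy)
  curves <- as_tibble(curves)
  key <- do.call(paste, curves[by])
  out <- purrr::pmap_dfr(pairs, function(a, b, ...) {
    purrr::map_dfr(sort(unique(curves$generation)), function(g) {
      ca <- curves[key == a & curves$generation == g, ]
      cb <- curves[key == b & curves$generation == g, ]
      if (nrow(ca) == 0 || nrow(cb) == 0) {
        abort(paste0("No curve found for pair (", a, ", ", b, ") generation ", g, "."),
              class = "pcm_stratum_not_found")
      }
      cmp <- compare_flight_curves(ca, cb, endpoint_policy, labels = c(a, b))
      mutate(tidy(cmp), a = a, b = b, generation = g, .before = 1)
    })
  })
  attr(out, "n_comparisons") <- nrow(out)
  out
}
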