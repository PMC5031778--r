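#' Detect the biofix (first sustained moth capture)
#'
#' The biofix anchors degree-day accumulation for the flight models. It is
#' operationalized as the earliest trap check whose total capture reaches
#' `min_count` and is confirmed by at least one further capture within the
#' next `confirm_within` checks, so an isolated early moth does not set the
#' anchor.
#'
#' @param records Trap-capture data frame with columns `check_date`, `males`,
#'   `females` (and usually `site`, `orchard_type`, `lure`, `trap_id`).
#'   Counts are summed over all rows sharing a check date, so filter or
#'   group the records first if a per-site or per-stratum biofix is wanted.
#' @param min_count Minimum total capture at the triggering check (default 1).
#' @param confirm_within Number of subsequent checks within which at least one
#'   more capture must occur (default 2).
#' @param sex Which sexes to count; biofix is conventionally set from male
#'   captures.
#' @return One-row tibble: `biofix_date`, `trigger_count`, `confirm_date`,
#'   `confirm_count`, `min_count`, `confirm_within`.
#' @examples
#' rec <- tibble::tibble(
#'   check_date = as.Date("2007-04-20") + c(0, 3, 7, 10, 14),
#'   males = c(0, 0, 2, 3, 1), females = 0
#' )
#' detect_biofix(rec)
#' @export
detect_biofix <- function(records, min_count = 1, confirm_within = 2,
                          sex = c("male", "female", "both")) {
  sex <- match.arg(sex)
  records <- as_trap_table(records, require_strata = FALSE)
  totals <- records |>
    mutate(.count = sex_counts(records, sex)) |>
    group_by(check_date = .data$check_date) |>
    summarise(total = sum(.data$.count), .groups = "drop") |>
    arrange(.data$check_date)
  n <- nrow(totals)
  for (i in seq_len(n)) {
    if (totals$total[i] < min_count) next
    if (i + 1 > n) next  # triggering capture at the last check cannot be confirmed
    ahead <- seq(i + 1, min(i + confirm_within, n))
    hit <- ahead[totals$total[ahead] >= 1]
    if (length(hit) > 0) {
      return(tibble(
        biofix_date = totals$check_date[i],
        trigger_count = totals$total[i],
        confirm_date = totals$check_date[hit[1]],
        confirm_count = totals$total[hit[1]],
        min_count = min_count,
        confirm_within = confirm_within
      ))
    }
  }
  abort("No check satisfies the sustained-capture rule; biofix undefined.",
        class = "pcm_no_biofix")
}

#' Mean seasonal capture per trap with standard errors
#'
#' For each check date (within each stratum) computes the mean per-trap
#' capture and its standard error across traps, the quantity plotted in
#' seasonal flight-pattern figures.
#'
#' @inheritParams detect_biofix
#' @param by Stratifying columns (default orchard type and lure).
#' @param orchard_type,lure Optional filters; an empty result after filtering
#'   is an error.
#' @return Tibble with the `by` columns plus `check_date`, `n_traps`,
#'   `mean_capture`, `sem` (`NA` when only one trap).
#' @export
mean_seasonal_capture <- function(records, sex = c("male", "female", "both"),
                                  by = c("orchard_type", "lure"),
                                  orchard_type = NULL, lure = NULL) {
  sex <- match.arg(sex)
  records <- as_trap_table(records)
  if (!is.null(orchard_type)) {
    records <- filter(records, .data$orchard_type %in% !!orchard_type)
  }
  if (!is.null(lure)) records <- filter(records, .data$lure %in% !!lure)
  if (nrow(records) == 0) {
    abort("No trap records in the requested stratum.",
          class = "pcm_stratum_not_found")
  }
  records$.count <- sex_counts(records, sex)
  records |>
    group_by(across(all_of(by)), check_date = .data$check_date) |>
    summarise(
      n_traps = dplyr::n(),
      mean_capture = mean(.data$.count),
      sem = sd(.data$.count) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    arrange(across(all_of(by)), .data$check_date)
}

#' Generation windows on the degree-day axis
#'
#' Builds the generation-flight windows used to partition captures. Windows
#' are expressed as degree-days from biofix and are half-open,
#' upper-inclusive: generation 2 runs over `(cutoff1, cutoff2]`. Generation 1
#' additionally includes the biofix check itself (DD = 0). The conventional
#' cutoff pairs are the PETE-derived "constrained" values (460, 1057.5) and
#' the empirically observed "unconstrained" values (540, 1185), the
#' mid-ranges of the published intervals ~455-465/~1055-1060 DD and
#' ~530-550/~1175-1195 DD.
#'
#' @param mode `"constrained"`, `"unconstrained"`, or `"custom"` (then
#'   `cutoffs` must be supplied).
#' @param cutoffs Length-2 increasing numeric vector: end of the generation-1
#'   and generation-2 flights, DD from biofix. Overrides the mode defaults.
#' @return Tibble with columns `generation`, `dd_start`, `dd_cutoff`, `mode`.
#' @export
generation_windows <- function(mode = c("unconstrained", "constrained", "custom"),
                               cutoffs = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutoffs)) {
    cutoffs <- switch(mode,
      constrained = c(460, 1057.5),
      unconstrained = c(540, 1185),
      custom = abort("`mode = \"custom\"` requires explicit `cutoffs`.")
    )
  }
  if (length(cutoffs) != 2 || !is.numeric(cutoffs) || any(cutoffs <= 0) ||
      diff(cutoffs) <= 0) {
    abort("`cutoffs` must be two increasing positive degree-day values.",
          class = "pcm_window_error")
  }
  tibble(
    generation = c(1L, 2L),
    dd_start = c(0, cutoffs[1]),
    dd_cutoff = cutoffs,
    mode = mode
  )
}

#' Assign captures to generation flights by degree-day windows
#'
#' @param captures Data frame carrying a `cumulative_dd` column (degree-days
#'   from biofix), e.g. trap records joined to a degree-day series via
#'   [attach_degree_days()].
#' @param windows Output of [generation_windows()], or a length-2 cutoff
#'   vector passed on to it.
#' @return `captures` with an integer `generation` column: 1 or 2 within the
#'   windows (boundary captures go to the earlier generation), 3 for the
#'   partial third flight beyond the generation-2 cutoff, which is excluded
#'   from modelling.
#' @export
split_generations <- function(captures, windows = generation_windows()) {
  if (is.numeric(windows)) windows <- generation_windows("custom", cutoffs = windows)
  if (!all(c("generation", "dd_start", "dd_cutoff") %in% names(windows)) ||
      nrow(windows) != 2 ||
      windows$dd_start[2] != windows$dd_cutoff[1] ||
      any(windows$dd_start >= windows$dd_cutoff)) {
    abort("`windows` must be two ordered, contiguous generation windows.",
          class = "pcm_window_error")
  }
  captures <- as_tibble(captures)
  if (!"cumulative_dd" %in% names(captures)) {
    abort("`captures` must carry a `cumulative_dd` column (see `attach_degree_days()`).")
  }
  dd <- captures$cumulative_dd
  captures$generation <- dplyr::case_when(
    dd <= windows$dd_cutoff[1] ~ 1L,  # generation 1 includes the biofix check
    dd <= windows$dd_cutoff[2] ~ 2L,
    TRUE ~ 3L                         # partial third flight, not modelled
  )
  captures
}

#' Join trap records to a degree-day series
#'
#' Attaches `cumulative_dd` (degree-days from biofix) to each trap record by
#' check date. Checks falling before the series anchor (pre-biofix) are
#' dropped, since the flight curves are defined from biofix onward.
#'
#' @inheritParams detect_biofix
#' @param dd_series Output of [accumulate_degree_days()].
#' @return `records` restricted to dates covered by `dd_series`, with a
#'   `cumulative_dd` column added.
#' @export
attach_degree_days <- function(records, dd_series) {
  records <- as_trap_table(records, require_strata = FALSE)
  joined <- left_join(records,
                      select(dd_series, date = "date", "cumulative_dd"),
                      by = c(check_date = "date"))
  dropped <- sum(is.na(joined$cumulative_dd))
  if (dropped > 0) {
    inform(paste0("Dropped ", dropped,
                  " record(s) outside the degree-day series (pre-biofix or post-season)."))
  }
  filter(joined, !is.na(.data$cumulative_dd))
}

#' Cumulative-percent capture curve for one generation flight
#'
#' Collapses a generation's captures into the (X, Y) pairs of the logistic
#' flight model: X the cumulative degree-days from biofix at each check, Y
#' the running capture total as a proportion of the generation's total.
#' Checks sharing a degree-day value (e.g. across cold spells or multiple
#' traps) are pooled, so X is strictly increasing; the final Y is exactly 1.
#'
#' @param captures Data frame with `cumulative_dd` and count columns, e.g. one
#'   generation subset from [split_generations()].
#' @param sex Which counts enter the curve.
#' @return Tibble with columns `dd`, `cum_prop`, `n_total`.
#' @export
cumulative_percent <- function(captures, sex = c("male", "female", "both")) {
  sex <- match.arg(sex)
  captures <- as_tibble(captures)
  if (!"cumulative_dd" %in% names(captures)) {
    abort("`captures` must carry a `cumulative_dd` column.")
  }
  counts <- sex_counts(captures, sex)
  curve <- tibble(dd = captures$cumulative_dd, count = counts) |>
    group_by(dd = .data$dd) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$dd)
  total <- sum(curve$count)
  if (total <= 0) {
    abort("No captures in this generation; cumulative curve undefined.",
          class = "pcm_empty_generation")
  }
  tibble(
    dd = curve$dd,
    cum_prop = cumsum(curve$count) / total,
    n_total = total
  )
}

#' Average cumulative curves across sites on a common degree-day grid
#'
#' Computes the mean cumulative-percent capture across sites: each site's
#' curve is linearly interpolated onto a shared degree-day grid (0 before a
#' site's first check, 1 after its last) and the site curves are averaged
#' point-wise, so each site carries equal weight.
#'
#' @param curves Data frame of per-site curves with columns `site`, `dd`,
#'   `cum_prop`.
#' @param grid Degree-day grid; defaults to the union of the sites' check
#'   degree-days.
#' @return Tibble with columns `dd`, `cum_prop`, `n_sites`.
#' @export
average_curves <- function(curves, grid = NULL) {
  curves <- as_tibble(curves)
  if (!all(c("site", "dd", "cum_prop") %in% names(curves))) {
    abort("`curves` must have columns `site`, `dd`, `cum_prop`.")
  }
  grid <- sort(unique(grid %||% curves$dd))
  per_site <- curves |>
    group_by(site = .data$site) |>
    dplyr::group_map(~ {
      if (nrow(.x) == 1) {
        ifelse(grid < .x$dd, 0, 1)
      } else {
        stats::approx(.x$dd, .x$cum_prop, xout = grid,
                      yleft = 0, yright = 1)$y
      }
    })
  tibble(
    dd = grid,
    cum_prop = rowMeans(do.call(cbind, per_site)),
    n_sites = length(per_site)
  )
}

#' Full trap-to-curve pipeline
#'
#' Convenience wrapper running biofix detection, degree-day accumulation,
#' generation partitioning and curve construction for each stratum: the raw
#' material for [fit_flight_model()].
#'
#' @inheritParams detect_biofix
#' @param temps Daily temperature table (see [accumulate_degree_days()]).
#' @param windows Generation windows (see [generation_windows()]).
#' @param by Stratifying columns for separate curves.
#' @param biofix Optional pre-determined biofix date; when `NULL` it is
#'   detected from the pooled records with `min_count`/`confirm_within`.
#' @param lower,upper Degree-day thresholds.
#' @return Tibble of curves with the `by` columns plus `generation`, `dd`,
#'   `cum_prop`, `n_total`; the biofix result is attached as attribute
#'   `"biofix"`.
#' @export
build_flight_curves <- function(records, temps,
                                windows = generation_windows(),
                                sex = c("male", "female", "both"),
                                by = c("orchard_type", "lure"),
                                biofix = NULL,
                                min_count = 1, confirm_within = 2,
                                lower = 10, upper = 31) {
  sex <- match.arg(sex)
  records <- as_trap_table(records)
  if (is.null(biofix)) {
    biofix <- detect_biofix(records, min_count, confirm_within)
  } else if (!is.data.frame(biofix)) {
    biofix <- tibble(biofix_date = as.Date(biofix))
  }
  dd_series <- accumulate_degree_days(temps, anchor = biofix$biofix_date,
                                      lower = lower, upper = upper)
  with_dd <- attach_degree_days(records, dd_series) |>
    split_generations(windows) |>
    filter(.data$generation %in% c(1L, 2L))
  curves <- with_dd |>
    group_by(across(all_of(by)), generation = .data$generation) |>
    dplyr::group_modify(~ {
      # strata or windows without any capture yield no curve (the fit would
      # refuse them anyway); keep the pipeline usable on sparse strata
      if (sum(sex_counts(.x, sex)) <= 0) return(tibble()) else cumulative_percent(.x, sex = sex)
    }) |>
    ungroup()
  attr(curves, "biofix") <- biofix
  attr(curves, "windows") <- windows
  curves
}

# ---- internal helpers -------------------------------------------------------

as_trap_table <- function(records, require_strata = TRUE) {
  records <- as_tibble(records)
  need <- c("check_date", "males", "females")
  if (require_strata) need <- c("check_date", "orchard_type", "lure", "males", "females")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Trap records are missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  records$check_date <- as.Date(records$check_date)
  if (any(records$males < 0, na.rm = TRUE) || any(records$females < 0, na.rm = TRUE)) {
    abort("Capture counts must be non-negative.", class = "pcm_invalid_record")
  }
  records
}

sex_counts <- function(records, sex) {
  switch(sex,
    male = records$males,
    female = records$females,
    both = records$males + records$females
  )
}
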