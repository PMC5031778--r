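test_that("biofix is the earliest sustained capture and no earlier check qualifies", {
  rec <- make_records(c(0, 0, 2, 3, 1))
  b <- detect_biofix(rec, min_count = 1, confirm_within = 2)
  expect_equal(b$biofix_date, rec$check_date[3])   # the "2", confirmed by the "3"

  rec2 <- make_records(c(0, 1, 0, 0, 0, 4, 2))
  b2 <- detect_biofix(rec2, min_count = 1, confirm_within = 2)
  expect_equal(b2$biofix_date, rec2$check_date[6]) # isolated "1" unconfirmed

  # minimality, checked exhaustively: every earlier check fails the rule
  totals <- c(0, 1, 0, 0, 0, 4, 2)
  earlier <- which(rec2$check_date < b2$biofix_date)
  for (i in earlier) {
    qualifies <- totals[i] >= 1 &&
      any(totals[seq(i + 1, min(i + 2, length(totals)))] >= 1)
    expect_false(qualifies)
  }

  expect_error(detect_biofix(make_records(rep(0, 6))), class = "pcm_no_biofix")
})

test_that("mean seasonal capture matches the textbook mean/SEM across traps", {
  two_traps <- dplyr::bind_rows(
    make_records(c(4, 8)),
    dplyr::mutate(make_records(c(6, 2)), trap_id = "S1_CM_L2_T2")
  )
  msc <- mean_seasonal_capture(two_traps)
  expect_equal(msc$mean_capture, c(5, 5))
  expect_equal(msc$sem, c(1, 3))                  # sd/sqrt(2) of (4,6) and (8,2)

  one_trap <- mean_seasonal_capture(make_records(c(4, 8)))
  expect_true(all(is.na(one_trap$sem)))            # SEM undefined for one trap

  set.seed(33)
  counts <- matrix(rpois(40, 6), nrow = 4)         # 4 traps x 10 checks
  recs <- dplyr::bind_rows(lapply(1:4, function(tr) {
    dplyr::mutate(make_records(counts[tr, ]), trap_id = paste0("T", tr))
  }))
  msc2 <- mean_seasonal_capture(recs)
  expect_equal(msc2$mean_capture, colMeans(counts))
  expect_equal(msc2$sem, apply(counts, 2, sd) / 2)

  expect_error(mean_seasonal_capture(recs, orchard_type = "abandoned"),
               class = "pcm_stratum_not_found")
})

test_that("generation windows partition captures with an upper-inclusive boundary", {
  caps <- tibble::tibble(cumulative_dd = c(100, 500, 540, 1100, 1185, 1400),
                         males = 1, females = 0)
  got <- split_generations(caps, generation_windows("unconstrained"))
  expect_equal(got$generation, c(1L, 1L, 1L, 2L, 2L, 3L))

  # totals conserved across the partition
  expect_equal(sum(table(got$generation)), nrow(caps))

  expect_error(split_generations(caps, c(1185, 540)), class = "pcm_window_error")
  w <- generation_windows("constrained")
  expect_equal(w$dd_cutoff, c(460, 1057.5))
  expect_equal(w$dd_start[2], w$dd_cutoff[1])
})

test_that("cumulative percent runs to exactly 1 and is scale invariant", {
  caps <- tibble::tibble(cumulative_dd = c(10, 50, 90), males = c(2, 3, 5),
                         females = 0)
  cv <- cumulative_percent(caps)
  expect_equal(cv$cum_prop, c(0.2, 0.5, 1.0))
  expect_equal(cv$n_total, rep(10, 3))

  one <- cumulative_percent(tibble::tibble(cumulative_dd = 5, males = 7, females = 0))
  expect_equal(one$cum_prop, 1)

  set.seed(44)
  caps2 <- tibble::tibble(cumulative_dd = sort(runif(20, 0, 500)),
                          males = rpois(20, 5) + 1, females = 0)
  base <- cumulative_percent(caps2)
  scaled <- cumulative_percent(dplyr::mutate(caps2, males = males * 7))
  expect_equal(base$cum_prop, scaled$cum_prop)
  # brute-force running-sum oracle
  expect_equal(base$cum_prop, cumsum(caps2$males) / sum(caps2$males))
  expect_true(all(diff(base$dd) > 0))

  expect_error(cumulative_percent(tibble::tibble(cumulative_dd = 1, males = 0,
                                                 females = 0)),
               class = "pcm_empty_generation")
})

test_that("checks sharing a degree-day value are pooled so x stays strictly increasing", {
  caps <- tibble::tibble(cumulative_dd = c(0, 0, 20, 20, 60),
                         males = c(1, 2, 3, 4, 10), females = 0)
  cv <- cumulative_percent(caps)
  expect_equal(cv$dd, c(0, 20, 60))
  expect_equal(cv$cum_prop, c(0.15, 0.5, 1))
})

test_that("site-averaged curves stay in [0, 1] and end at 1", {
  set.seed(55)
  curves <- dplyr::bind_rows(lapply(1:3, function(s) {
    dd <- sort(runif(12, 0, 500))
    p <- sort(runif(11, 0.02, 0.98))
    tibble::tibble(site = paste0("S", s), dd = dd, cum_prop = c(p, 1))
  }))
  avg <- average_curves(curves)
  expect_true(all(avg$cum_prop >= 0 & avg$cum_prop <= 1))
  expect_true(all(diff(avg$cum_prop) >= -1e-12))
  expect_equal(avg$cum_prop[nrow(avg)], 1)
  expect_equal(avg$n_sites[1], 3)
})

test_that("the trap-to-curve pipeline produces one curve per stratum and generation", {
  sim <- simulate_scenario(scenario_config("abandoned", seed = 9,
                                           noise = "poisson"))
  curves <- suppressMessages(build_flight_curves(sim$traps, sim$temps))
  expect_true(all(c("orchard_type", "lure", "generation", "dd", "cum_prop",
                    "n_total") %in% names(curves)))
  expect_setequal(unique(curves$generation), c(1L, 2L))
  finals <- curves |>
    dplyr::group_by(lure, generation) |>
    dplyr::summarise(last = dplyr::last(cum_prop), .groups = "drop")
  expect_true(all(finals$last == 1))
  expect_s3_class(attr(curves, "biofix"), "tbl_df")
})
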