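test_that("product-limit estimate matches the hand computation", {
  # subjects: event at 2, censor at 4, event at 6, censor at 8
  curve <- km_estimate(c(2, 4, 6, 8), c(TRUE, FALSE, TRUE, FALSE))
  s_at <- function(t) curve$survival[max(which(curve$time <= t))]
  expect_equal(s_at(2), 3 / 4)
  expect_equal(s_at(4), 3 / 4)
  expect_equal(s_at(6), 3 / 8)
  expect_equal(curve$survival[curve$time == 0], 1)
})

test_that("degenerate curves behave: all censored, and no censoring = 1 - ECDF", {
  all_cens <- km_estimate(c(3, 6, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(all_cens$survival == 1))
  expect_true(all(all_cens$ci_low == 1 & all_cens$ci_high == 1))

  t <- c(1, 2, 2, 5, 7)
  no_cens <- km_estimate(t, rep(TRUE, 5))
  for (u in unique(t)) {
    expect_equal(no_cens$survival[no_cens$time == u], mean(t > u))
  }
})

test_that("risk-table bookkeeping conserves subjects", {
  set.seed(11)
  for (rep in 1:5) {
    smp <- random_censored_sample(60)
    curve <- km_estimate(smp$time, smp$event)
    expect_equal(curve$n_risk[1], 60)
    # n_risk(next) = n_risk - n_event - n_censor at every time
    expect_equal(curve$n_risk[-1],
                 (curve$n_risk - curve$n_event - curve$n_censor)[-nrow(curve)])
    expect_equal(sum(curve$n_event) + sum(curve$n_censor), 60)
    # survival non-increasing, CI brackets the estimate
    expect_true(all(diff(curve$survival) <= 1e-12))
    expect_true(all(curve$ci_low <= curve$survival + 1e-12))
    expect_true(all(curve$ci_high >= curve$survival - 1e-12))
  }
})

test_that("estimator agrees with the survival package on random censored data", {
  set.seed(2024)
  for (rep in 1:20) {
    smp <- random_censored_sample(sample(5:80, 1))
    curve <- km_estimate(smp$time, smp$event)
    fit <- survival::survfit(survival::Surv(smp$time, smp$event) ~ 1,
                             conf.type = "log-log")
    mine <- curve[match(fit$time, curve$time), ]
    expect_equal(mine$survival, fit$surv, tolerance = 1e-12)
    expect_equal(mine$n_risk, fit$n.risk)
    expect_equal(mine$n_event, fit$n.event)
    ok <- !is.na(fit$lower)
    expect_equal(mine$ci_low[ok], fit$lower[ok], tolerance = 1e-8)
    expect_equal(mine$ci_high[ok], fit$upper[ok], tolerance = 1e-8)
  }
})

test_that("events and censorings tied at one time resolve events-first", {
  # at t = 5: one event and one censor; the censored subject still counts
  # in the risk set, so the factor is (1 - 1/3), not (1 - 1/2)
  curve <- km_estimate(c(5, 5, 9), c(TRUE, FALSE, TRUE))
  expect_equal(curve$survival[curve$time == 5], 2 / 3)
  expect_equal(curve$n_risk[curve$time == 5], 3)
  expect_equal(curve$survival[curve$time == 9], 2 / 3 * 0)
})

test_that("input validation rejects empty and negative inputs", {
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
  expect_error(km_estimate(c(1, -2), c(TRUE, TRUE)), "non-negative")
  expect_error(km_estimate(c(1, 2), TRUE), "equal length")
})

test_that("stratified curves equal km_estimate per stratum and reflect hazard ordering", {
  cfg <- synthetic_config(n_patients = 600, seed = 21)
  cohort <- generate_cohort(cfg)
  outcomes <- derive_outcomes(cohort)

  # single stratum reduces to km_estimate
  ks_none <- km_by_strata(cohort, outcomes, strata = "none",
                          which = "primary_composite")
  te <- with(outcomes, {
    t0 <- ifelse(is.na(primary_composite_time), censor_time, primary_composite_time)
    list(time = t0, event = !is.na(primary_composite_time))
  })
  direct <- km_estimate(te$time, te$event, outcome_label = "primary_composite")
  expect_equal(as.data.frame(ks_none$curves$primary_composite$all),
               as.data.frame(direct))

  # endovascular stratum has the larger generating complication hazard, so
  # its event-free curve must lie below the open curve at the horizon
  ks <- km_by_strata(cohort, outcomes, strata = "approach",
                     which = "aortic_event")
  s_final <- vapply(ks$curves$aortic_event,
                    function(cv) cv$survival[nrow(cv)], numeric(1))
  expect_lt(s_final[["endovascular"]], s_final[["open"]])

  expect_error(km_by_strata(cohort, outcomes, strata = "pathology"))
  expect_error(km_by_strata(cohort, outcomes, which = "not_an_outcome"),
               "unknown outcome")
})

test_that("grid-table cumulative events count events up to each grid time", {
  cohort <- generate_cohort(synthetic_config(n_patients = 150, seed = 9))
  outcomes <- derive_outcomes(cohort)
  ks <- km_by_strata(cohort, outcomes, strata = "none", which = "reintervention")
  tab <- ks$grid_table
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$cum_events[i],
                 sum(!is.na(outcomes$reintervention_time) &
                       outcomes$reintervention_time <= tab$months[i]))
  }
  expect_equal(tab$n_risk[tab$months == 0], 150)
})
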