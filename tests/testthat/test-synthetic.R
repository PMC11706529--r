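zero_hazards <- function(k = 6) {
  matrix(0, k, 6, dimnames = list(NULL, c("HC", "HR", "HD", "CR", "CD", "RD")))
}

test_that("zero hazards and zero censoring keep every patient healthy", {
  cfg <- synthetic_config(n_patients = 40, seed = 2,
                          hazards = zero_hazards(), censor_prob = 0)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$events), 0L)
  expect_true(all(attr(cohort, "true_trajectory") == 1L))
  expect_true(all(cohort$baseline$followup_end_months == 36))
  occ <- true_occupancy(cfg)
  expect_true(all(occ$H == 1))
})

test_that("a certain first-interval death absorbs the whole cohort at 6 months", {
  h <- zero_hazards()
  h[1, "HD"] <- 1
  cfg <- synthetic_config(n_patients = 30, seed = 5, hazards = h,
                          censor_prob = 0)
  cohort <- generate_cohort(cfg)
  expect_true(all(attr(cohort, "true_trajectory")[, 2:7] == 4L))
  deaths <- cohort$events[cohort$events$kind == "death", ]
  expect_equal(nrow(deaths), 30L)
  expect_true(all(deaths$time_months == 6))
  expect_equal(true_occupancy(cfg)$D[-1], rep(1, 6))
})

test_that("identical (config, seed) reproduce the cohort bit-for-bit", {
  cfg <- synthetic_config(n_patients = 120, seed = 17)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$baseline, c2$baseline)
  expect_identical(c1$events, c2$events)
  expect_identical(attr(c1, "true_trajectory"), attr(c2, "true_trajectory"))
  c3 <- generate_cohort(synthetic_config(n_patients = 120, seed = 18))
  expect_false(identical(c1$events, c3$events))
})

test_that("per-patient substreams make records independent of cohort size", {
  small <- generate_cohort(synthetic_config(n_patients = 25, seed = 9))
  large <- generate_cohort(synthetic_config(n_patients = 80, seed = 9))
  expect_identical(attr(small, "true_trajectory"),
                   attr(large, "true_trajectory")[1:25, ])
  b_small <- small$baseline
  b_large <- large$baseline[1:25, ]
  rownames(b_large) <- NULL
  b_small$patient_id <- b_large$patient_id <- NULL  # widths differ with n
  expect_identical(b_small, b_large)
})

test_that("every generated trajectory is a valid path in the transition graph", {
  cohort <- generate_cohort(synthetic_config(n_patients = 400, seed = 23))
  traj <- attr(cohort, "true_trajectory")
  ok <- matrix(FALSE, 4, 4)
  ok[1, ] <- TRUE; ok[2, 2:4] <- TRUE; ok[3, 3:4] <- TRUE; ok[4, 4] <- TRUE
  for (k in 1:6) {
    pair <- stats::complete.cases(traj[, k], traj[, k + 1])
    expect_true(all(ok[traj[pair, k:(k + 1), drop = FALSE]]))
  }
  # event times are scheduled-visit multiples under visit detection
  expect_true(all(cohort$events$time_months %% 6 == 0))
  expect_true(all(cohort$events$time_months > 0))
})

test_that("exact detection places events strictly inside their interval", {
  cfg <- synthetic_config(n_patients = 300, seed = 31, detection = "exact")
  cohort <- generate_cohort(cfg)
  traj <- attr(cohort, "true_trajectory")
  out <- derive_outcomes(cohort)
  cnt <- discretize(out, 6, 36)
  # the discretized states must reproduce the generating trajectory wherever
  # it is observed (round-trip through the event log)
  s_from_outcomes <- function(t) {
    st <- rep(1L, nrow(out))
    st[!is.na(out$aortic_event_time) & out$aortic_event_time <= t] <- 2L
    st[!is.na(out$reintervention_time) & out$reintervention_time <= t] <- 3L
    st[!is.na(out$death_time) & out$death_time <= t] <- 4L
    st
  }
  for (k in 0:6) {
    obs <- !is.na(traj[, k + 1])
    expect_equal(s_from_outcomes(k * 6)[obs], unname(traj[obs, k + 1]))
  }
})

test_that("empirical transition fractions match the generating hazards", {
  h <- zero_hazards()
  h[, "HC"] <- 0.08; h[, "HR"] <- 0.03; h[, "HD"] <- 0.01
  h[, "CR"] <- 0.15; h[, "CD"] <- 0.05; h[, "RD"] <- 0.06
  cfg <- synthetic_config(n_patients = 8000, seed = 42, hazards = h,
                          censor_prob = 0.05)
  cohort <- generate_cohort(cfg)
  traj <- attr(cohort, "true_trajectory")
  cells <- list(HC = c(1, 2), HR = c(1, 3), HD = c(1, 4),
                CR = c(2, 3), CD = c(2, 4), RD = c(3, 4))
  for (k in 1:6) {
    from <- traj[, k]
    to <- traj[, k + 1]
    for (nm in names(cells)) {
      o <- cells[[nm]][1]; d <- cells[[nm]][2]
      n_o <- sum(from == o & !is.na(to))
      if (n_o < 50) next
      p_hat <- sum(from == o & to == d, na.rm = TRUE) / n_o
      p <- h[k, nm]
      expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n_o) + 1e-12)
    }
  }
})

test_that("true occupancy equals propagation of the generating matrices", {
  cfg <- synthetic_config(n_patients = 10, seed = 1)
  occ <- true_occupancy(cfg)
  w <- cfg$frac_endovascular
  by_hand <- (1 - w) * as.matrix(propagate_occupancy(generating_model(cfg, "open"))[, c("H", "C", "R", "D")]) +
    w * as.matrix(propagate_occupancy(generating_model(cfg, "endovascular"))[, c("H", "C", "R", "D")])
  expect_equal(as.matrix(occ[, c("H", "C", "R", "D")]), by_hand)

  # single-transition arithmetic: H->C = 0.1 for one step
  h <- zero_hazards(1)
  h[1, "HC"] <- 0.1
  cfg1 <- synthetic_config(n_patients = 10, seed = 1, horizon = 6, hazards = h,
                           censor_prob = 0)
  expect_equal(as.numeric(true_occupancy(cfg1)[2, c("H", "C", "R", "D")]),
               c(0.9, 0.1, 0, 0))
})

test_that("invalid configurations are rejected with the offending cell named", {
  h <- zero_hazards()
  h[3, "HC"] <- 1.2
  expect_error(synthetic_config(hazards = h), "transition HC in interval 3")
  h <- zero_hazards()
  h[2, "HC"] <- 0.7; h[2, "HR"] <- 0.4
  expect_error(synthetic_config(hazards = h), "state H exceed 1 in interval 2")
  expect_error(synthetic_config(censor_prob = c(0.1, -0.2)),
               "censoring in interval 2")
  expect_error(synthetic_config(horizon = 35), "multiple")
  expect_error(synthetic_config(frac_endovascular = 1.4), "proportion")
})
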