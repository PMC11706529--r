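outcomes_row <- function(patient_id = "A", aortic = NA, reint = NA,
                         death = NA, censor = 36) {
  data.frame(patient_id = patient_id, aortic_event_time = aortic,
             aortic_event_kind = NA_character_, reintervention_time = reint,
             death_time = death, primary_composite_time = NA_real_,
             primary_composite_type = NA_character_, censor_time = censor)
}

counts_for <- function(counts, interval, origin) {
  counts[counts$interval == interval & counts$origin == origin, ]
}

test_that("interval assignment follows the (t, t+6] convention", {
  # event at month 7: H at the 6-month boundary, C at the 12-month boundary
  cnt <- discretize(outcomes_row(aortic = 7), 6, 36)
  expect_equal(counts_for(cnt, 1, "H")$to_H, 1)
  expect_equal(counts_for(cnt, 2, "H")$to_C, 1)
  # event at exactly 6.0 months belongs to the first interval
  cnt <- discretize(outcomes_row(aortic = 6), 6, 36)
  expect_equal(counts_for(cnt, 1, "H")$to_C, 1)
  expect_equal(counts_for(cnt, 2, "C")$n_at_risk, 1)
})

test_that("censoring mid-interval removes the patient from that risk set", {
  cnt <- discretize(outcomes_row(censor = 9), 6, 36)
  i1 <- counts_for(cnt, 1, "H")
  expect_equal(i1$n_at_risk, 1); expect_equal(i1$n_censored, 0)
  expect_equal(i1$to_H, 1)
  i2 <- counts_for(cnt, 2, "H")
  expect_equal(i2$n_at_risk, 1); expect_equal(i2$n_censored, 1)
  expect_equal(i2$to_H + i2$to_C + i2$to_R + i2$to_D, 0)
  i3 <- counts_for(cnt, 3, "H")
  expect_equal(i3$n_at_risk, 0)
})

test_that("multiple events in one interval land the patient in the worst state", {
  cnt <- discretize(outcomes_row(aortic = 7, reint = 11), 6, 36)
  expect_equal(counts_for(cnt, 2, "H")$to_R, 1)
  expect_equal(counts_for(cnt, 2, "H")$to_C, 0)
  # dead patients stay absorbed through the horizon
  cnt <- discretize(outcomes_row(death = 8, censor = 8), 6, 36)
  expect_equal(counts_for(cnt, 2, "H")$to_D, 1)
  expect_equal(counts_for(cnt, 5, "D")$to_D, 1)
})

test_that("horizon must be a positive multiple of the interval length", {
  expect_error(discretize(outcomes_row(), 6, 33), "multiple")
  expect_error(discretize(outcomes_row(), 6, 0), "multiple")
})

test_that("transition probabilities follow the complete-case formula", {
  # 100 H at risk: 5 -> C, 2 -> R, 1 -> D, 2 censored => denominator 98
  rows <- lapply(1:100, function(i) {
    a <- if (i <= 5) 4 else NA
    r <- if (i > 5 && i <= 7) 4 else NA
    d <- if (i == 8) 4 else NA
    cen <- if (i %in% 9:10) 3 else 6
    outcomes_row(sprintf("P%03d", i), aortic = a, reint = r, death = d,
                 censor = cen)
  })
  cnt <- discretize(do.call(rbind, rows), 6, 6)
  fit <- estimate_transition_matrices(cnt)
  expect_equal(fit$matrices[[1]]["H", ],
               c(H = 90 / 98, C = 5 / 98, R = 2 / 98, D = 1 / 98))
})

test_that("no events and no censoring yield the identity matrix", {
  cnt <- discretize(do.call(rbind, lapply(1:10, function(i) {
    outcomes_row(sprintf("P%02d", i))
  })), 6, 12)
  # never-occupied states are expected to be empty: no warning
  expect_silent(fit <- estimate_transition_matrices(cnt))
  expect_equal(fit$matrices[[1]], diag(4), ignore_attr = TRUE)
  expect_equal(fit$matrices[[2]], diag(4), ignore_attr = TRUE)
})

test_that("a risk set emptied by censoring triggers the identity-row warning", {
  # the only complicated patient is censored within interval 2: origin C has
  # a patient at risk there but a zero complete-case denominator
  out <- rbind(outcomes_row("A", aortic = 4, censor = 8),
               outcomes_row("B", censor = 36))
  cnt <- discretize(out, 6, 12)
  expect_warning(fit <- estimate_transition_matrices(cnt),
                 "interval 2 origin C")
  expect_equal(fit$matrices[[2]]["C", ], c(H = 0, C = 1, R = 0, D = 0))
})

test_that("estimating from censoring-free trajectories reproduces empirical fractions exactly", {
  cfg <- synthetic_config(n_patients = 40, seed = 33, censor_prob = 0)
  cohort <- generate_cohort(cfg)
  traj <- attr(cohort, "true_trajectory")
  cnt <- discretize(derive_outcomes(cohort), 6, 36)
  fit <- suppressWarnings(estimate_transition_matrices(cnt))
  s <- aorta_states()
  for (k in seq_len(6)) {
    for (o in 1:3) {
      from <- traj[, k] == o
      if (!any(from)) next
      for (dst in 1:4) {
        frac <- sum(from & traj[, k + 1] == dst) / sum(from)
        expect_equal(fit$matrices[[k]][s[o], s[dst]], frac)
      }
    }
  }
})

test_that("estimated matrices are row-stochastic with exact structural zeros", {
  cohort <- generate_cohort(synthetic_config(n_patients = 800, seed = 13))
  fit <- suppressWarnings(
    estimate_transition_matrices(discretize(derive_outcomes(cohort)))
  )
  for (m in fit$matrices) {
    expect_equal(rowSums(m), c(H = 1, C = 1, R = 1, D = 1), tolerance = 1e-12)
    expect_identical(m["C", "H"], 0)
    expect_identical(unname(m["R", c("H", "C")]), c(0, 0))
    expect_identical(unname(m["D", c("H", "C", "R")]), c(0, 0, 0))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("occupancy propagation is the matrix product, with conserved mass", {
  # identity model: occupancy stays at the initial distribution
  id_model <- mcm(list(diag(4), diag(4)))
  occ <- propagate_occupancy(id_model, c(0.7, 0.2, 0.05, 0.05))
  expect_true(all(occ$H == 0.7 & occ$C == 0.2))

  # single step equals the H row of the matrix
  m <- diag(4); m[1, ] <- c(0.9, 0.06, 0.03, 0.01)
  occ1 <- propagate_occupancy(mcm(list(m)))
  expect_equal(as.numeric(occ1[2, c("H", "C", "R", "D")]),
               c(0.9, 0.06, 0.03, 0.01))

  # two steps equal the hand-multiplied product
  model <- toy_model(2)
  occ2 <- propagate_occupancy(model)
  hand <- c(1, 0, 0, 0) %*% model$matrices[[1]] %*% model$matrices[[2]]
  expect_equal(as.numeric(occ2[3, c("H", "C", "R", "D")]), as.numeric(hand))

  # conservation and monotone absorption on a generic model
  occ <- propagate_occupancy(toy_model(6))
  expect_equal(rowSums(occ[, c("H", "C", "R", "D")]), rep(1, 7),
               ignore_attr = TRUE)
  expect_true(all(diff(occ$D) >= 0))
  expect_true(all(diff(occ$H) <= 0))

  expect_error(propagate_occupancy(toy_model(2), c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("simulation is seeded, reproducible and degenerate-safe", {
  model <- toy_model(3)
  s1 <- simulate_cohort(model, 500, seed = 99)
  s2 <- simulate_cohort(model, 500, seed = 99)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(as.data.frame(s1$occupancy), as.data.frame(s2$occupancy))

  id_sim <- simulate_cohort(mcm(list(diag(4))), 50, seed = 1)
  expect_true(all(id_sim$trajectories == 1L))

  absorb <- diag(4); absorb[1, ] <- c(0, 0, 0, 1)
  d_sim <- simulate_cohort(mcm(list(absorb, diag(4))), 50, seed = 1)
  expect_true(all(d_sim$trajectories[, 2:3] == 4L))
  expect_equal(d_sim$occupancy$D[2], 1)

  expect_error(simulate_cohort(model, 0, seed = 1), "positive integer")
})

test_that("simulated occupancy rows are exact relative frequencies summing to 1", {
  sim <- simulate_cohort(toy_model(4), 321, seed = 5)
  counts <- t(apply(sim$trajectories, 2, tabulate, nbins = 4))
  expect_equal(as.matrix(sim$occupancy[, c("H", "C", "R", "D")]),
               counts / 321, ignore_attr = TRUE)
})

test_that("model construction rejects malformed matrices", {
  bad <- diag(4); bad[2, 1] <- 0.1; bad[2, 2] <- 0.9
  expect_error(mcm(list(bad)), "forbidden transition")
  bad2 <- diag(4); bad2[1, 1] <- 0.5
  expect_error(mcm(list(bad2)), "row-stochastic")
  expect_error(mcm(list()), "non-empty")
})
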