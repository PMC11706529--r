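#' Tabulate interval transition counts from derived outcomes
#'
#' Discretizes per-patient outcome times onto a grid of fixed-length follow-up
#' intervals and counts, for every interval and origin state, how many
#' patients were at risk, how many were censored within the interval, and how
#' many moved to each destination state.
#'
#' @param outcomes Data frame from [derive_outcomes()] (columns
#'   `aortic_event_time`, `reintervention_time`, `death_time`, `censor_time`).
#' @param interval_length Interval length in months (default 6).
#' @param horizon Total follow-up horizon in months; must be a positive
#'   multiple of `interval_length` (default 36).
#' @return A data frame of class `"interval_counts"` with one row per
#'   (interval, origin state): columns `interval`, `origin`, `n_at_risk`,
#'   `n_censored`, `to_H`, `to_C`, `to_R`, `to_D`.
#' @details Intervals are half-open on the left, `((k-1)L, kL]`, so an event
#'   at exactly `kL` months belongs to interval `k` — "at 6 months" summaries
#'   therefore include findings of the 6-month visit itself. A patient's
#'   state at a boundary is the worst state (D > R > C) reached by that time.
#'   A patient censored strictly before the end of an interval, with no event
#'   in it, is removed from that interval's risk-set denominator (complete
#'   cases within interval); a patient whose `censor_time` falls exactly on
#'   the interval's start is likewise censored within it, having completed
#'   only the preceding interval.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 200, seed = 1))
#' counts <- discretize(derive_outcomes(cohort))
#' head(counts)
discretize <- function(outcomes, interval_length = 6, horizon = 36) {
  if (!is.data.frame(outcomes)) stop("'outcomes' must be a data frame from derive_outcomes()")
  need <- c("aortic_event_time", "reintervention_time", "death_time", "censor_time")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop("outcomes is missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(interval_length) || interval_length <= 0) {
    stop("'interval_length' must be positive")
  }
  k_steps <- horizon / interval_length
  if (!is.numeric(horizon) || horizon <= 0 || abs(k_steps - round(k_steps)) > 1e-9) {
    stop("'horizon' must be a positive multiple of 'interval_length'")
  }
  k_steps <- as.integer(round(k_steps))

  a <- outcomes$aortic_event_time
  r <- outcomes$reintervention_time
  d <- outcomes$death_time
  cen <- outcomes$censor_time
  if (any(is.na(cen))) stop("censor_time must be present for every patient")

  # state at boundary t: worst of the events that have occurred by t
  state_at <- function(t) {
    st <- rep(1L, length(cen))
    st[!is.na(a) & a <= t] <- 2L
    st[!is.na(r) & r <= t] <- 3L
    st[!is.na(d) & d <= t] <- 4L
    st
  }

  s <- aorta_states()
  rows <- vector("list", k_steps)
  for (k in seq_len(k_steps)) {
    t0 <- (k - 1) * interval_length
    t1 <- k * interval_length
    prev <- state_at(t0)
    cur <- state_at(t1)
    # present in interval k: observed through t0 (censor_time >= t0) or dead
    present <- cen >= t0 | prev == 4L
    moved <- cur != prev
    # censored within interval: alive, no event in the interval, follow-up
    # ends before t1 (censor exactly at t0 counts here, not in interval k-1)
    cens_in <- present & prev != 4L & !moved & cen < t1
    at_risk <- present
    tab <- matrix(0L, 4L, 4L, dimnames = list(s, s))
    n_risk <- integer(4L)
    n_cens <- integer(4L)
    for (o in 1:4) {
      sel <- at_risk & prev == o
      n_risk[o] <- sum(sel)
      n_cens[o] <- sum(cens_in & prev == o)
      obs <- sel & !cens_in
      if (any(obs)) tab[o, ] <- tabulate(cur[obs], nbins = 4L)
    }
    rows[[k]] <- data.frame(
      interval = k, origin = s,
      n_at_risk = n_risk, n_censored = n_cens,
      to_H = tab[, 1L], to_C = tab[, 2L], to_R = tab[, 3L], to_D = tab[, 4L]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            interval_length = interval_length, horizon = horizon,
            class = c("interval_counts", "data.frame"))
}

#' Estimate per-interval transition matrices
#'
#' Turns interval transition counts into a non-homogeneous Markov chain by
#' the complete-case estimator: for every interval and origin state,
#' `p(origin -> dest) = transitions / (n_at_risk - n_censored_in_interval)`,
#' with the diagonal receiving the remainder. An origin state with an empty
#' (post-censoring) risk set yields the identity row, with a warning.
#'
#' @param counts An `"interval_counts"` data frame from [discretize()].
#' @return An `"mcm"` model (see [mcm()]).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 500, seed = 7))
#' fit <- estimate_transition_matrices(discretize(derive_outcomes(cohort)))
#' fit$matrices[[1]]
estimate_transition_matrices <- function(counts) {
  if (!inherits(counts, "interval_counts")) {
    stop("'counts' must come from discretize()")
  }
  num_cols <- c("n_at_risk", "n_censored", "to_H", "to_C", "to_R", "to_D")
  if (any(as.matrix(counts[num_cols]) < 0)) stop("counts must be non-negative")
  dest <- as.matrix(counts[c("to_H", "to_C", "to_R", "to_D")])
  if (any(rowSums(dest) + counts$n_censored > counts$n_at_risk)) {
    stop("destination counts plus censored exceed the risk set for some origin")
  }
  s <- aorta_states()
  intervals <- sort(unique(counts$interval))
  empty <- character(0)
  seen <- c(H = FALSE, C = FALSE, R = FALSE, D = FALSE)
  mats <- lapply(intervals, function(k) {
    m <- diag(4)
    dimnames(m) <- list(s, s)
    sub <- counts[counts$interval == k, , drop = FALSE]
    for (o in s) {
      row <- sub[sub$origin == o, , drop = FALSE]
      if (nrow(row) == 0L) next
      denom <- row$n_at_risk - row$n_censored
      if (denom <= 0) {
        # identity row: no information = no movement. Only warn when
        # information was actually lost (the state was occupied before, or
        # everyone in it this interval was censored); a state nobody has
        # reached yet is expected to be empty.
        if (o != "D" && (row$n_at_risk > 0 || seen[[o]])) {
          empty <<- c(empty, sprintf("interval %d origin %s", k, o))
        }
        next
      }
      seen[o] <<- TRUE
      trans <- as.numeric(row[1, c("to_H", "to_C", "to_R", "to_D")])
      p <- trans / denom
      off <- setdiff(s, o)
      m[o, off] <- p[match(off, s)]
      m[o, o] <- 1 - sum(m[o, off])
    }
    m
  })
  if (length(empty)) {
    warning("empty risk set, identity row used: ", paste(empty, collapse = "; "))
  }
  mcm(mats, interval_length = attr(counts, "interval_length"))
}

#' Propagate state occupancy exactly through a model
#'
#' Computes the exact probability of each state at every interval boundary by
#' left-multiplying the initial distribution through the ordered transition
#' matrices: occupancy at step `k` is `initial %*% M_1 %*% ... %*% M_k`.
#'
#' @param model An `"mcm"` object.
#' @param initial Initial distribution over (H, C, R, D); must sum to 1.
#'   Default: everyone starts healthy.
#' @return An `"occupancy_table"` data frame (step, months, H, C, R, D) with
#'   provenance `"exact"`.
#' @export
#' @examples
#' m <- diag(4); m[1, ] <- c(0.9, 0.06, 0.03, 0.01)
#' propagate_occupancy(mcm(list(m)))
propagate_occupancy <- function(model, initial = c(1, 0, 0, 0)) {
  stopifnot(inherits(model, "mcm"))
  if (length(initial) != 4L || !is.numeric(initial)) {
    stop("'initial' must be a numeric distribution over the 4 states")
  }
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-9) {
    stop("'initial' must be non-negative and sum to 1")
  }
  k <- n_intervals(model)
  occ <- matrix(NA_real_, k + 1L, 4L)
  occ[1L, ] <- initial
  v <- matrix(initial, nrow = 1L)
  for (i in seq_len(k)) {
    v <- v %*% model$matrices[[i]]
    occ[i + 1L, ] <- v
  }
  check_occupancy(new_occupancy_table(occ, model$interval_length, "exact"))
}

#' Simulate patient trajectories through a model
#'
#' Draws `n` independent state trajectories starting from H at step 0, one
#' categorical draw per patient and interval from the interval's transition
#' matrix, and tabulates the relative frequency of each state at every step.
#'
#' @param model An `"mcm"` object.
#' @param n Number of simulated patients (>= 1).
#' @param seed Integer seed; the same (model, n, seed) reproduces the
#'   identical simulation.
#' @return List with `trajectories` (an `n` x (steps + 1) integer matrix of
#'   state codes 1=H .. 4=D) and `occupancy` (an `"occupancy_table"` of exact
#'   relative frequencies, provenance `"simulated"`).
#' @export
#' @examples
#' m <- diag(4); m[1, ] <- c(0.9, 0.06, 0.03, 0.01)
#' sim <- simulate_cohort(mcm(list(m, m)), n = 1000, seed = 42)
#' sim$occupancy
simulate_cohort <- function(model, n, seed) {
  stopifnot(inherits(model, "mcm"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer")
  }
  n <- as.integer(n)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("'seed' must be a single integer")
  }
  seed <- as.integer(seed)
  k <- n_intervals(model)
  set.seed(seed)
  traj <- matrix(1L, n, k + 1L)
  state <- rep(1L, n)
  for (i in seq_len(k)) {
    m <- model$matrices[[i]]
    new_state <- state
    for (o in 1:3) {   # D is absorbing, nothing to draw
      idx <- which(state == o)
      if (!length(idx)) next
      new_state[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = m[o, ])
    }
    state <- new_state
    traj[, i + 1L] <- state
  }
  occ <- t(apply(traj, 2L, tabulate, nbins = 4L)) / n
  occupancy <- check_occupancy(
    new_occupancy_table(occ, model$interval_length, "simulated",
                        n = n, seed = seed)
  )
  list(trajectories = traj, occupancy = occupancy)
}
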