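#' Default per-interval discrete hazards for the synthetic generator
#'
#' Per-approach tables of discrete per-interval transition probabilities over
#' a 36-month horizon in 6-month steps. The endovascular-like stratum has a
#' markedly larger early complication hazard (endoleaks dominate its early
#' follow-up), the open-like stratum low event rates throughout; both are
#' illustrative shapes, not a reconstruction of any fitted model.
#'
#' @param horizon Horizon in months (default 36).
#' @param interval_length Interval length in months (default 6).
#' @return Named list with elements `open` and `endovascular`, each a numeric
#'   matrix with one row per interval and columns `HC`, `HR`, `HD`, `CR`,
#'   `CD`, `RD` (discrete probabilities of the corresponding transition).
#' @export
default_hazards <- function(horizon = 36, interval_length = 6) {
  k <- as.integer(round(horizon / interval_length))
  pad <- function(x) rep_len(x, k)
  mk <- function(HC, HR, HD, CR, CD, RD) {
    cbind(HC = pad(HC), HR = pad(HR), HD = pad(HD),
          CR = pad(CR), CD = pad(CD), RD = pad(RD))
  }
  list(
    open = mk(
      HC = c(0.012, 0.010, 0.006, 0.005, 0.004, 0.004),
      HR = c(0.012, 0.010, 0.006, 0.005, 0.004, 0.004),
      HD = c(0.003, 0.004, 0.005, 0.006, 0.007, 0.008),
      CR = c(0.12, 0.10, 0.08, 0.08, 0.08, 0.08),
      CD = c(0.03, 0.03, 0.03, 0.04, 0.04, 0.05),
      RD = c(0.04, 0.03, 0.03, 0.03, 0.04, 0.04)
    ),
    endovascular = mk(
      HC = c(0.100, 0.060, 0.030, 0.020, 0.015, 0.012),
      HR = c(0.035, 0.030, 0.012, 0.008, 0.006, 0.005),
      HD = c(0.012, 0.010, 0.010, 0.010, 0.012, 0.014),
      CR = c(0.20, 0.15, 0.10, 0.08, 0.08, 0.08),
      CD = c(0.03, 0.03, 0.03, 0.04, 0.04, 0.05),
      RD = c(0.05, 0.04, 0.03, 0.03, 0.04, 0.04)
    )
  )
}

hazard_transitions <- function() c("HC", "HR", "HD", "CR", "CD", "RD")

#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of patients discharged after elective aortic surgery:
#' its size, surgical-approach and anatomical-level mix, the per-interval
#' discrete transition hazards that drive events, the per-interval
#' administrative censoring probability, and whether event times are detected
#' exactly or only at scheduled surveillance visits.
#'
#' @param n_patients Number of patients (default 464, a realistic two-year
#'   single-centre elective volume).
#' @param seed Root integer seed; per-patient substreams are derived from
#'   `(seed, patient index)` so a patient's record does not depend on cohort
#'   size or ordering.
#' @param frac_endovascular Proportion treated endovascularly (default 0.25).
#' @param frac_abdominal Named numeric vector: probability of abdominal (vs
#'   thoracic) pathology per approach (default `c(open = 0.32,
#'   endovascular = 0.80)`).
#' @param interval_length Months between scheduled visits (default 6).
#' @param horizon Follow-up horizon in months; positive multiple of
#'   `interval_length` (default 36).
#' @param hazards Either a single matrix (one row per interval, columns `HC`,
#'   `HR`, `HD`, `CR`, `CD`, `RD`) applied to every patient, or a named list
#'   with one such matrix per approach (`open`, `endovascular`). Default
#'   [default_hazards()].
#' @param censor_prob Per-interval probability of administrative censoring,
#'   recycled to the number of intervals. The default
#'   `c(0.02, 0.02, 0.02, 0.15, 0.25, 0.35)` keeps early censoring light and
#'   lets it rise steeply after 18 months of follow-up.
#' @param detection `"visit"` (events recorded at the next scheduled visit,
#'   i.e. times are multiples of `interval_length`) or `"exact"` (times drawn
#'   uniformly within the interval).
#' @return A validated list of class `"synthetic_config"`.
#' @details Probabilities must lie in \[0, 1\] and, for every origin state
#'   and interval, outgoing hazards must sum to at most 1; violations raise
#'   an error naming the interval and transition group.
#' @export
#' @examples
#' cfg <- synthetic_config(n_patients = 100, seed = 1)
#' cohort <- generate_cohort(cfg)
synthetic_config <- function(n_patients = 464,
                             seed = 1,
                             frac_endovascular = 0.25,
                             frac_abdominal = c(open = 0.32, endovascular = 0.80),
                             interval_length = 6,
                             horizon = 36,
                             hazards = NULL,
                             censor_prob = c(0.02, 0.02, 0.02, 0.15, 0.25, 0.35),
                             detection = c("visit", "exact")) {
  detection <- match.arg(detection)
  if (!is.numeric(n_patients) || n_patients < 1 || n_patients != round(n_patients)) {
    stop("'n_patients' must be a positive integer")
  }
  if (!is.numeric(seed) || length(seed) != 1L) stop("'seed' must be a single integer")
  k <- horizon / interval_length
  if (!is.numeric(horizon) || horizon <= 0 || abs(k - round(k)) > 1e-9) {
    stop("'horizon' must be a positive multiple of 'interval_length'")
  }
  k <- as.integer(round(k))
  if (!is.numeric(frac_endovascular) || frac_endovascular < 0 || frac_endovascular > 1) {
    stop("'frac_endovascular' must be a proportion in [0, 1]")
  }
  if (is.null(names(frac_abdominal)) ||
      !all(approach_levels() %in% names(frac_abdominal)) ||
      any(frac_abdominal < 0 | frac_abdominal > 1)) {
    stop("'frac_abdominal' must be proportions named by approach (open, endovascular)")
  }
  if (is.null(hazards)) hazards <- default_hazards(horizon, interval_length)
  if (is.matrix(hazards)) {
    hazards <- list(open = hazards, endovascular = hazards)
  }
  if (!is.list(hazards) || !all(approach_levels() %in% names(hazards))) {
    stop("'hazards' must be a matrix or a list with elements 'open' and 'endovascular'")
  }
  groups <- list(H = c("HC", "HR", "HD"), C = c("CR", "CD"), R = "RD")
  for (ap in approach_levels()) {
    h <- hazards[[ap]]
    if (!is.matrix(h) || !all(hazard_transitions() %in% colnames(h))) {
      stop(sprintf("hazards$%s must be a matrix with columns %s", ap,
                   paste(hazard_transitions(), collapse = ", ")))
    }
    if (nrow(h) != k) {
      stop(sprintf("hazards$%s must have one row per interval (%d)", ap, k))
    }
    for (tr in hazard_transitions()) {
      bad <- which(h[, tr] < 0 | h[, tr] > 1)
      if (length(bad)) {
        stop(sprintf("invalid probability for transition %s in interval %d (hazards$%s)",
                     tr, bad[1], ap))
      }
    }
    for (origin in names(groups)) {
      tot <- rowSums(h[, groups[[origin]], drop = FALSE])
      bad <- which(tot > 1 + 1e-12)
      if (length(bad)) {
        stop(sprintf(
          "outgoing probabilities from state %s exceed 1 in interval %d (hazards$%s: %s)",
          origin, bad[1], ap, paste(groups[[origin]], collapse = "+")))
      }
    }
    hazards[[ap]] <- h[, hazard_transitions(), drop = FALSE]
  }
  censor_prob <- rep_len(censor_prob, k)
  bad <- which(censor_prob < 0 | censor_prob > 1)
  if (length(bad)) {
    stop(sprintf("invalid probability for censoring in interval %d", bad[1]))
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         frac_endovascular = frac_endovascular,
         frac_abdominal = frac_abdominal[approach_levels()],
         interval_length = interval_length, horizon = horizon,
         n_steps = k, hazards = hazards, censor_prob = censor_prob,
         detection = detection),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d patients, %d x %g-month intervals, seed %d, detection '%s'\n",
    x$n_patients, x$n_steps, x$interval_length, x$seed, x$detection))
  cat(sprintf("  endovascular fraction %.2f; abdominal fraction open %.2f / endovascular %.2f\n",
              x$frac_endovascular, x$frac_abdominal[["open"]],
              x$frac_abdominal[["endovascular"]]))
  cat("  per-interval censoring: ", paste(format(x$censor_prob), collapse = " "), "\n", sep = "")
  invisible(x)
}

# Deterministic per-patient substream seed. Plain integer hashing; exact in
# double arithmetic (all intermediates < 2^53).
substream_seed <- function(seed, i) {
  h <- (abs(as.double(seed)) %% 2147483647) * 48271
  h <- (h + as.double(i) * 69621 + 1) %% 2147483647
  as.integer(h)
}

# Transition matrix for one approach stratum and interval from a hazard row.
hazard_matrix <- function(hrow) {
  m <- diag(4)
  m[1, ] <- c(1 - hrow[["HC"]] - hrow[["HR"]] - hrow[["HD"]],
              hrow[["HC"]], hrow[["HR"]], hrow[["HD"]])
  m[2, 2:4] <- c(1 - hrow[["CR"]] - hrow[["CD"]], hrow[["CR"]], hrow[["CD"]])
  m[3, 3:4] <- c(1 - hrow[["RD"]], hrow[["RD"]])
  dimnames(m) <- list(aorta_states(), aorta_states())
  m
}

#' Transition model implied by a synthetic configuration
#'
#' @param config A `"synthetic_config"`.
#' @param approach `"open"` or `"endovascular"`: which stratum's hazards to
#'   use.
#' @return An `"mcm"` built from the generating hazards (censoring ignored).
#' @export
generating_model <- function(config, approach = c("open", "endovascular")) {
  stopifnot(inherits(config, "synthetic_config"))
  approach <- match.arg(approach)
  h <- config$hazards[[approach]]
  mcm(lapply(seq_len(nrow(h)), function(k) hazard_matrix(h[k, ])),
      interval_length = config$interval_length)
}

#' Exact state occupancy implied by the generating hazards
#'
#' Closed-form ground truth for parameter-recovery tests: propagates the
#' generating transition matrices exactly (censoring ignored), mixing the
#' approach strata by `frac_endovascular`.
#'
#' @param config A `"synthetic_config"`.
#' @return An `"occupancy_table"` with provenance `"exact"`.
#' @export
#' @examples
#' true_occupancy(synthetic_config(n_patients = 10, seed = 1))
true_occupancy <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$frac_endovascular
  occ_open <- propagate_occupancy(generating_model(config, "open"))
  occ_endo <- propagate_occupancy(generating_model(config, "endovascular"))
  cols <- c("H", "C", "R", "D")
  mixed <- (1 - w) * as.matrix(occ_open[, cols]) + w * as.matrix(occ_endo[, cols])
  check_occupancy(new_occupancy_table(mixed, config$interval_length, "exact"))
}

# Event-kind mixture given a new complication, by approach. Endoleaks only
# occur after endovascular repair; open-repair complications are anastomotic
# aneurysms or residual-aneurysm growth.
complication_kind_probs <- function(approach) {
  if (approach == "endovascular") {
    c(endoleak_Ia = 0.12, endoleak_Ib = 0.06, endoleak_II = 0.50,
      endoleak_III = 0.08, endoleak_IV = 0.04,
      new_aneurysm = 0.10, diameter_progression = 0.10)
  } else {
    c(new_aneurysm = 0.65, diameter_progression = 0.35)
  }
}

#' Generate a seeded synthetic cohort
#'
#' Simulates patients one 6-month interval at a time with a single
#' categorical draw per patient-interval over censoring, the allowed state
#' transitions and staying put. Censoring competes with events: the censor
#' cell has probability `c_k` and each transition cell `(1 - c_k) * h`, so
#' the complete-case estimator in [estimate_transition_matrices()] is exactly
#' unbiased for the generating hazards. The true (uncensored portion of the)
#' state trajectory is attached for use as a recovery oracle.
#'
#' @param config A `"synthetic_config"`.
#' @return An `"aorta_cohort"` with attributes `true_trajectory` (n x
#'   (steps + 1) integer matrix of state codes 1=H..4=D, `NA` after
#'   censoring), `censor_step` (interval index of the censoring draw, `NA` if
#'   none) and `config`.
#' @details All patients start healthy at discharge (time 0). With
#'   `detection = "visit"` every event time is the scheduled-visit time
#'   `k * interval_length`; with `"exact"`, times are uniform within the
#'   interval. A censoring draw in interval `k` ends follow-up mid-interval
#'   (at `(k-1)*L + L/2`), placing the patient among that interval's censored
#'   in [discretize()]. Generated records emulate the post-eligibility
#'   cohort: all exclusion flags are FALSE, ages are at least 18 and the CTA
#'   visit count is at least 2, so [apply_eligibility()] keeps every record.
#'   Identical `(config, seed)` reproduce the cohort bit-for-bit, and each
#'   patient's record is driven by a substream derived from
#'   `(seed, patient index)` only.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 50, seed = 11))
#' table(attr(cohort, "true_trajectory")[, 7], useNA = "ifany")
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  k_steps <- config$n_steps
  L <- config$interval_length

  # Phase 1: per-patient substreams -> fixed-size uniform/normal draw blocks,
  # so records are invariant to cohort size and ordering.
  u_cov <- matrix(NA_real_, n, 3L)
  z_age <- numeric(n)
  u_step <- matrix(NA_real_, n, k_steps)
  u_kind <- matrix(NA_real_, n, k_steps)
  u_time <- matrix(NA_real_, n, k_steps)
  u_delta <- matrix(NA_real_, n, k_steps)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    u_cov[i, ] <- stats::runif(3L)
    z_age[i] <- stats::rnorm(1L)
    u_step[i, ] <- stats::runif(k_steps)
    u_kind[i, ] <- stats::runif(k_steps)
    u_time[i, ] <- stats::runif(k_steps)
    u_delta[i, ] <- stats::runif(k_steps)
  }

  approach <- ifelse(u_cov[, 1L] < config$frac_endovascular, "endovascular", "open")
  level <- ifelse(u_cov[, 2L] < config$frac_abdominal[approach], "abdominal", "thoracic")
  pathology <- pathology_levels()[findInterval(u_cov[, 3L], c(0, 0.90, 0.925)) ]
  age_mean <- ifelse(approach == "endovascular", 75, 64)
  age_sd <- ifelse(approach == "endovascular", 9, 11)
  age <- pmin(95, pmax(18, round(age_mean + age_sd * z_age, 1)))

  # Phase 2: trajectories, one vectorized categorical comparison per step.
  state <- rep(1L, n)                      # 1=H 2=C 3=R 4=D
  traj <- matrix(NA_integer_, n, k_steps + 1L)
  traj[, 1L] <- 1L
  censor_step <- rep(NA_integer_, n)
  ev_pid <- list(); ev_kind <- list(); ev_time <- list(); ev_delta <- list()
  pid <- sprintf("P%0*d", nchar(n) + 1L, seq_len(n))
  dest_of <- list(H = c(C = 2L, R = 3L, D = 4L), C = c(R = 3L, D = 4L), R = c(D = 4L))
  haz_cols <- list(H = c("HC", "HR", "HD"), C = c("CR", "CD"), R = "RD")

  for (k in seq_len(k_steps)) {
    ck <- config$censor_prob[k]
    new_state <- state
    for (ap in approach_levels()) {
      h <- config$hazards[[ap]][k, ]
      for (o in 1:3) {
        onm <- aorta_states()[o]
        idx <- which(state == o & approach == ap & is.na(censor_step))
        if (!length(idx)) next
        probs <- c(ck, (1 - ck) * unname(h[haz_cols[[onm]]]))
        cum <- cumsum(probs)
        cell <- findInterval(u_step[idx, k], cum, left.open = TRUE) + 1L
        # cell 1 = censor, cells 2..(1+n_dest) = transitions, beyond = stay
        censor_step[idx[cell == 1L]] <- k
        dests <- dest_of[[onm]]
        moved <- cell >= 2L & cell <= 1L + length(dests)
        new_state[idx[moved]] <- unname(dests[cell[moved] - 1L])
      }
    }
    state <- new_state
    traj[, k + 1L] <- ifelse(is.na(censor_step) | censor_step > k,
                             state, NA_integer_)
    # events for transitions made this step (censored patients cannot move)
    prev <- traj[, k]
    cur <- traj[, k + 1L]
    trans <- which(!is.na(prev) & !is.na(cur) & cur != prev)
    if (length(trans)) {
      t_event <- if (config$detection == "visit") {
        rep(k * L, length(trans))
      } else {
        (k - 1) * L + u_time[trans, k] * L
      }
      for (j in seq_along(trans)) {
        i <- trans[j]
        if (cur[i] == 2L) {                       # new complication
          kp <- complication_kind_probs(approach[i])
          kind <- names(kp)[findInterval(u_kind[i, k], cumsum(kp), left.open = TRUE) + 1L]
          delta <- if (kind == "diameter_progression") 10 + 15 * u_delta[i, k] else NA_real_
          ev_pid[[length(ev_pid) + 1L]] <- pid[i]
          ev_kind[[length(ev_kind) + 1L]] <- kind
          ev_time[[length(ev_time) + 1L]] <- t_event[j]
          ev_delta[[length(ev_delta) + 1L]] <- delta
        } else if (cur[i] == 3L) {                # reintervention
          ev_pid[[length(ev_pid) + 1L]] <- pid[i]
          ev_kind[[length(ev_kind) + 1L]] <- "reintervention"
          ev_time[[length(ev_time) + 1L]] <- t_event[j]
          ev_delta[[length(ev_delta) + 1L]] <- NA_real_
        } else if (cur[i] == 4L) {                # death
          ev_pid[[length(ev_pid) + 1L]] <- pid[i]
          ev_kind[[length(ev_kind) + 1L]] <- "death"
          ev_time[[length(ev_time) + 1L]] <- t_event[j]
          ev_delta[[length(ev_delta) + 1L]] <- NA_real_
        }
      }
    }
  }

  events <- data.frame(
    patient_id = unlist(ev_pid, use.names = FALSE) %||% character(0),
    kind = unlist(ev_kind, use.names = FALSE) %||% character(0),
    time_months = unlist(ev_time, use.names = FALSE) %||% numeric(0),
    diameter_delta_mm = unlist(ev_delta, use.names = FALSE) %||% numeric(0)
  )

  death_time <- rep(NA_real_, n)
  if (nrow(events)) {
    de <- events[events$kind == "death", , drop = FALSE]
    death_time[match(de$patient_id, pid)] <- de$time_months
  }
  followup_end <- ifelse(!is.na(death_time), death_time,
                         ifelse(!is.na(censor_step),
                                (censor_step - 1) * L + L / 2, config$horizon))
  n_visits <- pmax(2L, as.integer(floor(followup_end / L + 1e-9)))

  baseline <- data.frame(
    patient_id = pid, approach = approach, level = level, pathology = pathology,
    age_years = age,
    history_of_dissection = FALSE, planned_further_surgery = FALSE,
    emergent = FALSE, in_hospital_aortic_event = FALSE,
    n_followup_visits_with_cta = n_visits,
    followup_end_months = followup_end
  )
  cohort <- aorta_cohort(baseline, events)
  rownames(traj) <- pid
  attr(cohort, "true_trajectory") <- traj
  attr(cohort, "censor_step") <- censor_step
  attr(cohort, "config") <- config
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
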