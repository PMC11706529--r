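# Builders for micro-cohorts and random inputs used across the suite.

baseline_row <- function(patient_id, approach = "open", level = "abdominal",
                         pathology = "aneurysm", age_years = 65,
                         history_of_dissection = FALSE,
                         planned_further_surgery = FALSE, emergent = FALSE,
                         in_hospital_aortic_event = FALSE,
                         n_followup_visits_with_cta = 6,
                         followup_end_months = 36) {
  data.frame(patient_id = patient_id, approach = approach, level = level,
             pathology = pathology, age_years = age_years,
             history_of_dissection = history_of_dissection,
             planned_further_surgery = planned_further_surgery,
             emergent = emergent,
             in_hospital_aortic_event = in_hospital_aortic_event,
             n_followup_visits_with_cta = n_followup_visits_with_cta,
             followup_end_months = followup_end_months)
}

event_row <- function(patient_id, kind, time_months, diameter_delta_mm = NA_real_) {
  data.frame(patient_id = patient_id, kind = kind, time_months = time_months,
             diameter_delta_mm = diameter_delta_mm)
}

micro_cohort <- function(baseline_rows, event_rows = NULL) {
  baseline <- do.call(rbind, baseline_rows)
  events <- if (length(event_rows)) do.call(rbind, event_rows) else NULL
  aorta_cohort(baseline, events)
}

# Random right-censored survival sample for estimator cross-checks.
random_censored_sample <- function(n) {
  t_event <- stats::rexp(n, rate = 1 / 12)
  t_cens <- stats::rexp(n, rate = 1 / 18)
  # coarse rounding creates heavy ties, including event/censor ties
  time <- round(pmin(t_event, t_cens) * 2) / 2
  list(time = time, event = t_event <= t_cens)
}

# A small valid non-homogeneous model with movement on every allowed cell.
toy_model <- function(k = 4, interval_length = 6) {
  mats <- lapply(seq_len(k), function(i) {
    m <- diag(4)
    m[1, ] <- c(1 - 0.05 - 0.02 * i / k, 0.03, 0.02, 0.02 * i / k)
    m[2, 2:4] <- c(0.85, 0.10, 0.05)
    m[3, 3:4] <- c(0.95, 0.05)
    m
  })
  mcm(mats, interval_length = interval_length)
}
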