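#' @keywords internal
approach_levels <- function() c("open", "endovascular")
level_levels <- function() c("thoracic", "abdominal")
pathology_levels <- function() c("aneurysm", "leriche", "penetrating_aortic_ulcer")

#' Event kinds recognised in the event log
#'
#' Endoleak subtypes Ia/Ib (landing zones), II (branch back-flow), III (graft
#' defect) and IV (graft porosity); new (e.g. anastomotic false) aneurysm;
#' diameter progression of a residual aneurysm; reintervention (open or
#' endovascular); and death of any cause.
#'
#' @return Character vector of valid `kind` values.
#' @export
event_kinds <- function() {
  c("endoleak_Ia", "endoleak_Ib", "endoleak_II", "endoleak_III", "endoleak_IV",
    "new_aneurysm", "diameter_progression", "reintervention", "death")
}

aortic_event_kinds <- function() {
  c("endoleak_Ia", "endoleak_Ib", "endoleak_II", "endoleak_III", "endoleak_IV",
    "new_aneurysm", "diameter_progression")
}

baseline_columns <- function() {
  c("patient_id", "approach", "level", "pathology", "age_years",
    "history_of_dissection", "planned_further_surgery", "emergent",
    "in_hospital_aortic_event", "n_followup_visits_with_cta",
    "followup_end_months")
}

event_columns <- function() {
  c("patient_id", "kind", "time_months", "diameter_delta_mm")
}

#' Assemble and validate a patient cohort
#'
#' A cohort is a pair of tables in long format: one baseline row per patient
#' (surgical approach, anatomical level, pathology, age, eligibility flags,
#' CTA follow-up visit count, end of follow-up) and zero or more event rows
#' per patient (kind, time in months from discharge, and the diameter change
#' for progression events).
#'
#' @param baseline Data frame with columns `patient_id`, `approach`
#'   (open/endovascular), `level` (thoracic/abdominal), `pathology`
#'   (aneurysm/leriche/penetrating_aortic_ulcer), `age_years`, logical flags
#'   `history_of_dissection`, `planned_further_surgery`, `emergent`,
#'   `in_hospital_aortic_event`, `n_followup_visits_with_cta`,
#'   `followup_end_months`.
#' @param events Data frame with columns `patient_id`, `kind` (see
#'   [event_kinds()]), `time_months`, `diameter_delta_mm` (NA except for
#'   `diameter_progression` rows). May have zero rows.
#' @return An object of class `"aorta_cohort"`: a list with elements
#'   `baseline` and `events`.
#' @details Validation errors name the offending table and row numbers.
#'   Enforced invariants: event patient ids appear in the baseline table;
#'   event times are non-negative and do not exceed the patient's
#'   `followup_end_months`; at most one death per patient and no events after
#'   it; `diameter_progression` rows carry a numeric `diameter_delta_mm`.
#' @export
aorta_cohort <- function(baseline, events = NULL) {
  if (!is.data.frame(baseline)) stop("'baseline' must be a data frame")
  if (is.null(events)) {
    events <- data.frame(patient_id = character(), kind = character(),
                         time_months = numeric(), diameter_delta_mm = numeric())
  }
  if (!is.data.frame(events)) stop("'events' must be a data frame")
  miss <- setdiff(baseline_columns(), names(baseline))
  if (length(miss)) stop("baseline table is missing columns: ", paste(miss, collapse = ", "))
  if (!"diameter_delta_mm" %in% names(events)) events$diameter_delta_mm <- NA_real_
  miss <- setdiff(event_columns(), names(events))
  if (length(miss)) stop("event table is missing columns: ", paste(miss, collapse = ", "))

  baseline <- baseline[, baseline_columns(), drop = FALSE]
  events <- events[, event_columns(), drop = FALSE]
  baseline$patient_id <- as.character(baseline$patient_id)
  events$patient_id <- as.character(events$patient_id)

  bad_rows <- function(table, rows, why) {
    stop(sprintf("%s table, row(s) %s: %s", table,
                 paste(rows, collapse = ", "), why), call. = FALSE)
  }
  if (anyDuplicated(baseline$patient_id)) {
    bad_rows("baseline", which(duplicated(baseline$patient_id)),
             "duplicate patient_id")
  }
  chk_enum <- function(col, valid) {
    bad <- which(!baseline[[col]] %in% valid)
    if (length(bad)) {
      bad_rows("baseline", bad, sprintf("'%s' must be one of: %s", col,
                                        paste(valid, collapse = ", ")))
    }
  }
  chk_enum("approach", approach_levels())
  chk_enum("level", level_levels())
  chk_enum("pathology", pathology_levels())
  for (col in c("history_of_dissection", "planned_further_surgery",
                "emergent", "in_hospital_aortic_event")) {
    baseline[[col]] <- as.logical(baseline[[col]])
    bad <- which(is.na(baseline[[col]]))
    if (length(bad)) bad_rows("baseline", bad, sprintf("'%s' must be TRUE/FALSE", col))
  }
  bad <- which(!is.finite(baseline$age_years) | baseline$age_years < 0)
  if (length(bad)) bad_rows("baseline", bad, "'age_years' must be a non-negative number")
  bad <- which(!is.finite(baseline$followup_end_months) | baseline$followup_end_months < 0)
  if (length(bad)) bad_rows("baseline", bad, "'followup_end_months' must be non-negative")
  bad <- which(!is.finite(baseline$n_followup_visits_with_cta) |
                 baseline$n_followup_visits_with_cta < 0)
  if (length(bad)) bad_rows("baseline", bad, "'n_followup_visits_with_cta' must be a non-negative count")

  if (nrow(events)) {
    bad <- which(!events$patient_id %in% baseline$patient_id)
    if (length(bad)) bad_rows("event", bad, "patient_id not present in baseline table")
    bad <- which(!events$kind %in% event_kinds())
    if (length(bad)) {
      bad_rows("event", bad, sprintf("'kind' must be one of: %s",
                                     paste(event_kinds(), collapse = ", ")))
    }
    bad <- which(!is.finite(events$time_months) | events$time_months < 0)
    if (length(bad)) bad_rows("event", bad, "'time_months' must be a non-negative number")
    fu <- baseline$followup_end_months[match(events$patient_id, baseline$patient_id)]
    bad <- which(events$time_months > fu + 1e-9)
    if (length(bad)) bad_rows("event", bad, "event time exceeds the patient's followup_end_months")

    deaths <- events[events$kind == "death", , drop = FALSE]
    dup <- names(which(table(deaths$patient_id) > 1L))
    if (length(dup)) {
      bad_rows("event", which(events$kind == "death" & events$patient_id %in% dup),
               "more than one death entry for a patient")
    }
    if (nrow(deaths)) {
      dtime <- deaths$time_months[match(events$patient_id, deaths$patient_id)]
      bad <- which(!is.na(dtime) & events$kind != "death" &
                     events$time_months > dtime + 1e-9)
      if (length(bad)) bad_rows("event", bad, "event recorded after the patient's death")
    }
  }
  rownames(baseline) <- NULL
  rownames(events) <- NULL
  structure(list(baseline = baseline, events = events), class = "aorta_cohort")
}

#' @export
print.aorta_cohort <- function(x, ...) {
  cat(sprintf("Aortic-surgery follow-up cohort: %d patients, %d recorded events\n",
              nrow(x$baseline), nrow(x$events)))
  tab <- table(x$baseline$approach)
  cat("  approach: ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n", sep = "")
  tab <- table(x$baseline$level)
  cat("  level:    ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

exclusion_criteria <- function() {
  c("age_under_18", "history_of_dissection", "planned_further_surgery",
    "emergent", "in_hospital_aortic_event", "fewer_than_two_cta_visits")
}

#' Apply the study eligibility cascade
#'
#' Excludes, in fixed documented order: patients younger than 18; history of
#' aortic dissection; planned further aortic surgery; emergent surgery (e.g.
#' rupture); an in-hospital aortic event after the index procedure; and fewer
#' than two follow-up visits with CTA imaging. Each excluded patient is
#' tallied under the first criterion that removes them, so the tally matches
#' a sequential flow-chart cascade.
#'
#' @param cohort An `"aorta_cohort"`.
#' @return List with `cohort` (the eligible sub-cohort, an `"aorta_cohort"`),
#'   `exclusions` (named integer vector, one entry per criterion in cascade
#'   order), `n_input` and `n_eligible`.
#' @details Idempotent: re-applying to the eligible cohort excludes no one.
#'   An empty input yields an empty cohort and an all-zero tally.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 50, seed = 3))
#' apply_eligibility(cohort)$exclusions
apply_eligibility <- function(cohort) {
  stopifnot(inherits(cohort, "aorta_cohort"))
  b <- cohort$baseline
  crit <- list(
    age_under_18 = b$age_years < 18,
    history_of_dissection = b$history_of_dissection,
    planned_further_surgery = b$planned_further_surgery,
    emergent = b$emergent,
    in_hospital_aortic_event = b$in_hospital_aortic_event,
    fewer_than_two_cta_visits = b$n_followup_visits_with_cta < 2
  )
  excluded_by <- rep(NA_character_, nrow(b))
  for (name in exclusion_criteria()) {
    hit <- crit[[name]] & is.na(excluded_by)
    excluded_by[hit] <- name
  }
  tally <- vapply(exclusion_criteria(),
                  function(nm) sum(excluded_by == nm, na.rm = TRUE), integer(1))
  keep_ids <- b$patient_id[is.na(excluded_by)]
  eligible <- aorta_cohort(
    b[is.na(excluded_by), , drop = FALSE],
    cohort$events[cohort$events$patient_id %in% keep_ids, , drop = FALSE]
  )
  list(cohort = eligible, exclusions = tally,
       n_input = nrow(b), n_eligible = length(keep_ids))
}

#' Derive outcome times from the event log
#'
#' Computes, per patient, the outcome times used by the survival
#' and multi-state analyses: the first aortic event (any endoleak subtype, a
#' new/anastomotic aneurysm, or diameter progression of at least 10 mm over
#' the immediate post-operative baseline), the first reintervention, death of
#' any cause, and the primary composite (earliest of the three).
#'
#' @param cohort An `"aorta_cohort"`.
#' @return Data frame with one row per patient: `patient_id`,
#'   `aortic_event_time`, `aortic_event_kind`, `reintervention_time`,
#'   `death_time`, `primary_composite_time`, `primary_composite_type`
#'   (`"death"`, `"reintervention"` or `"aortic_event"`), `censor_time`.
#'   Absent outcomes are `NA`; `censor_time` is the end of follow-up.
#' @details Diameter-progression events with a change below 10 mm are
#'   ignored; a progression event with a missing `diameter_delta_mm` is a
#'   validation error naming the row. Ties for the composite are broken by
#'   severity: death > reintervention > aortic event. The result does not
#'   depend on the ordering of the event rows.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 100, seed = 2))
#' head(derive_outcomes(cohort))
derive_outcomes <- function(cohort) {
  stopifnot(inherits(cohort, "aorta_cohort"))
  b <- cohort$baseline
  ev <- cohort$events

  dp <- ev$kind == "diameter_progression"
  bad <- which(dp & !is.finite(ev$diameter_delta_mm))
  if (length(bad)) {
    stop(sprintf("event table, row(s) %s: diameter_progression requires diameter_delta_mm",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  qualifies <- ev$kind %in% setdiff(aortic_event_kinds(), "diameter_progression") |
    (dp & ev$diameter_delta_mm >= 10)

  first_time <- function(sel) {
    out <- rep(NA_real_, nrow(b))
    if (!any(sel)) return(out)
    agg <- tapply(ev$time_months[sel], ev$patient_id[sel], min)
    out[match(names(agg), b$patient_id)] <- as.numeric(agg)
    out
  }
  aortic_time <- first_time(qualifies)
  reint_time <- first_time(ev$kind == "reintervention")
  death_time <- first_time(ev$kind == "death")

  # kind of the first qualifying aortic event (earliest time; ties broken by
  # the documented kind order so the result is order-invariant)
  aortic_kind <- rep(NA_character_, nrow(b))
  if (any(qualifies)) {
    sub <- ev[qualifies, , drop = FALSE]
    sub$kind <- factor(sub$kind, levels = aortic_event_kinds())
    sub <- sub[order(sub$patient_id, sub$time_months, sub$kind), , drop = FALSE]
    sub <- sub[!duplicated(sub$patient_id), , drop = FALSE]
    aortic_kind[match(sub$patient_id, b$patient_id)] <- as.character(sub$kind)
  }

  comp <- pmin(aortic_time, reint_time, death_time, na.rm = TRUE)
  comp[is.na(aortic_time) & is.na(reint_time) & is.na(death_time)] <- NA_real_
  type <- rep(NA_character_, nrow(b))
  has <- !is.na(comp)
  type[has & !is.na(aortic_time) & aortic_time == comp] <- "aortic_event"
  type[has & !is.na(reint_time) & reint_time == comp] <- "reintervention"
  type[has & !is.na(death_time) & death_time == comp] <- "death"

  data.frame(
    patient_id = b$patient_id,
    aortic_event_time = aortic_time,
    aortic_event_kind = aortic_kind,
    reintervention_time = reint_time,
    death_time = death_time,
    primary_composite_time = comp,
    primary_composite_type = type,
    censor_time = b$followup_end_months
  )
}
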