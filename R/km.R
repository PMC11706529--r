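#' Kaplan-Meier product-limit estimate
#'
#' From-scratch product-limit estimator with full risk-table bookkeeping and
#' 95% Greenwood confidence bands on the log(-log) (exponential) scale:
#' `S(t)` is the product over event times `u <= t` of `(1 - d_u / n_u)`.
#'
#' @param time Non-negative follow-up durations in months, one per subject.
#' @param event Logical (or 0/1) event indicator; `FALSE` means censored at
#'   `time`.
#' @param conf_level Confidence level for the Greenwood bands (default 0.95).
#' @param outcome_label,strata_label Labels carried on the returned curve.
#' @return A data frame of class `"km_curve"` with one row per distinct
#'   event/censoring time (plus a leading time-0 row where needed): columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`, `ci_low`,
#'   `ci_high`. Attributes: `outcome_label`, `strata_label`, `conf_level`,
#'   `n`.
#' @details Subjects with an event and subjects censored at the same time are
#'   all counted at risk at that time, with events resolved first (the
#'   standard tie convention). The variance of `log(-log S)` is Greenwood's
#'   sum divided by `log(S)^2` and the interval is `S^exp(+/- z * se)`, which
#'   respects the \[0, 1\] range. Where `S` is 1 (no events yet) the band is
#'   \[1, 1\]; where `S` is 0 it is \[0, 0\].
#' @export
#' @examples
#' km_estimate(c(2, 4, 6, 8), c(TRUE, FALSE, TRUE, FALSE))
km_estimate <- function(time, event, conf_level = 0.95,
                        outcome_label = "outcome", strata_label = NULL) {
  if (length(time) == 0L) stop("empty input: at least one subject is required")
  if (length(time) != length(event)) stop("'time' and 'event' must have equal length")
  if (!is.numeric(time) || any(!is.finite(time)) || any(time < 0)) {
    stop("'time' must be finite and non-negative")
  }
  event <- as.logical(event)
  if (any(is.na(event))) stop("'event' must be TRUE/FALSE")
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    stop("'conf_level' must be in (0, 1)")
  }

  n <- length(time)
  tt <- sort(unique(time))
  d <- vapply(tt, function(u) sum(time == u & event), numeric(1))
  cns <- vapply(tt, function(u) sum(time == u & !event), numeric(1))
  n_risk <- n - c(0, cumsum(d + cns))[seq_along(tt)]

  frac <- ifelse(d > 0, 1 - d / n_risk, 1)
  surv <- cumprod(frac)
  # Greenwood terms accumulate at event times only
  gterm <- ifelse(d > 0 & n_risk > d, d / (n_risk * (n_risk - d)), 0)
  gsum <- cumsum(gterm)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- ci_high <- numeric(length(tt))
  inner <- surv > 0 & surv < 1
  se_ll <- sqrt(gsum[inner]) / abs(log(surv[inner]))
  ci_low[inner] <- surv[inner]^exp(z * se_ll)
  ci_high[inner] <- surv[inner]^exp(-z * se_ll)
  ci_low[surv >= 1] <- 1; ci_high[surv >= 1] <- 1
  ci_low[surv <= 0] <- 0; ci_high[surv <= 0] <- 0

  out <- data.frame(time = tt, n_risk = n_risk, n_event = d, n_censor = cns,
                    survival = surv, ci_low = ci_low, ci_high = ci_high)
  if (min(tt) > 0) {
    out <- rbind(data.frame(time = 0, n_risk = n, n_event = 0, n_censor = 0,
                            survival = 1, ci_low = 1, ci_high = 1), out)
  }
  rownames(out) <- NULL
  structure(out, outcome_label = outcome_label, strata_label = strata_label,
            conf_level = conf_level, n = n,
            class = c("km_curve", "data.frame"))
}

#' @export
print.km_curve <- function(x, digits = 4, ...) {
  lab <- attr(x, "outcome_label")
  st <- attr(x, "strata_label")
  cat(sprintf("Kaplan-Meier curve: %s%s (n = %d, %.0f%% CI)\n", lab,
              if (is.null(st)) "" else paste0(", stratum ", st),
              attr(x, "n"), 100 * attr(x, "conf_level")))
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Outcomes available for survival analysis
#' @return Character vector of outcome selector names accepted by
#'   [km_by_strata()].
#' @export
km_outcomes <- function() {
  c("primary_composite", "death", "aortic_event", "reintervention",
    "endoleak", "new_aneurysm", "diameter_progression")
}

# (time, event) pair for one outcome from derived outcomes + the event log.
outcome_time_event <- function(cohort, outcomes, which) {
  b <- cohort$baseline
  ev <- cohort$events
  pick <- function(tm) {
    t_obs <- ifelse(is.na(tm), outcomes$censor_time, tm)
    list(time = t_obs, event = !is.na(tm))
  }
  first_kind <- function(kinds) {
    out <- rep(NA_real_, nrow(b))
    sel <- ev$kind %in% kinds
    if (any(sel)) {
      if (identical(kinds, "diameter_progression")) {
        sel <- sel & !is.na(ev$diameter_delta_mm) & ev$diameter_delta_mm >= 10
      }
      if (any(sel)) {
        agg <- tapply(ev$time_months[sel], ev$patient_id[sel], min)
        out[match(names(agg), b$patient_id)] <- as.numeric(agg)
      }
    }
    out
  }
  switch(which,
    primary_composite = pick(outcomes$primary_composite_time),
    death = pick(outcomes$death_time),
    aortic_event = pick(outcomes$aortic_event_time),
    reintervention = pick(outcomes$reintervention_time),
    endoleak = pick(first_kind(grep("^endoleak", event_kinds(), value = TRUE))),
    new_aneurysm = pick(first_kind("new_aneurysm")),
    diameter_progression = pick(first_kind("diameter_progression")),
    stop(sprintf("unknown outcome '%s'; valid outcomes: %s", which,
                 paste(km_outcomes(), collapse = ", ")))
  )
}

#' Stratified Kaplan-Meier curves with grid-point risk tables
#'
#' Fits one product-limit curve per outcome and stratum level, plus a risk
#' table at scheduled-visit grid points (numbers at risk, cumulative events,
#' cumulative censored).
#'
#' @param cohort An `"aorta_cohort"`.
#' @param outcomes Optional pre-computed result of [derive_outcomes()];
#'   derived from `cohort` when omitted.
#' @param strata `"none"`, `"approach"` (open vs endovascular) or `"level"`
#'   (thoracic vs abdominal).
#' @param which Outcome selectors (subset of [km_outcomes()]; default all).
#' @param grid_months Grid for the risk table (default every 6 months to the
#'   largest observed time).
#' @return List of class `"km_set"`: `curves` (nested list,
#'   `curves[[outcome]][[stratum]]` is a `"km_curve"`) and `grid_table` (data
#'   frame: outcome, stratum, months, n_risk, cum_events, cum_censored).
#' @details Numbers at risk at grid time `g` count subjects still under
#'   observation at `g` (observed time >= `g`); cumulative events count
#'   events with time <= `g`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 200, seed = 5))
#' ks <- km_by_strata(cohort, strata = "approach", which = "primary_composite")
#' ks$grid_table
km_by_strata <- function(cohort, outcomes = NULL,
                         strata = c("none", "approach", "level"),
                         which = km_outcomes(),
                         grid_months = NULL) {
  stopifnot(inherits(cohort, "aorta_cohort"))
  strata <- match.arg(strata)
  bad <- setdiff(which, km_outcomes())
  if (length(bad)) {
    stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(outcomes)) outcomes <- derive_outcomes(cohort)
  b <- cohort$baseline
  groups <- if (strata == "none") {
    list(all = rep(TRUE, nrow(b)))
  } else {
    vals <- b[[strata]]
    stats::setNames(lapply(unique(vals), function(v) vals == v), unique(vals))
  }
  curves <- list()
  grid_rows <- list()
  for (oc in which) {
    te <- outcome_time_event(cohort, outcomes, oc)
    if (is.null(grid_months)) {
      gm <- seq(0, max(te$time), by = 6)
    } else {
      gm <- grid_months
    }
    curves[[oc]] <- list()
    for (g in names(groups)) {
      sel <- groups[[g]]
      curves[[oc]][[g]] <- km_estimate(
        te$time[sel], te$event[sel],
        outcome_label = oc,
        strata_label = if (strata == "none") NULL else g
      )
      grid_rows[[length(grid_rows) + 1L]] <- data.frame(
        outcome = oc, stratum = g, months = gm,
        n_risk = vapply(gm, function(t0) sum(te$time[sel] >= t0), numeric(1)),
        cum_events = vapply(gm, function(t0) {
          sum(te$event[sel] & te$time[sel] <= t0)
        }, numeric(1)),
        cum_censored = vapply(gm, function(t0) {
          sum(!te$event[sel] & te$time[sel] <= t0)
        }, numeric(1))
      )
    }
  }
  grid_table <- do.call(rbind, grid_rows)
  rownames(grid_table) <- NULL
  structure(list(curves = curves, grid_table = grid_table, strata = strata),
            class = "km_set")
}

#' @export
print.km_set <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve set: %d outcome(s), stratified by %s\n",
              length(x$curves), x$strata))
  for (oc in names(x$curves)) {
    for (g in names(x$curves[[oc]])) {
      cv <- x$curves[[oc]][[g]]
      cat(sprintf("  %s / %s: n = %d, final S = %.4f\n", oc, g, attr(cv, "n"),
                  cv$survival[nrow(cv)]))
    }
  }
  invisible(x)
}
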