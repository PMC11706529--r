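# CSV dialect used throughout: UTF-8, comma separator, header row, "."
# decimal mark; months as the sole time unit.

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write / read a cohort in the two-table CSV dialect
#'
#' @param cohort An `"aorta_cohort"`.
#' @param baseline_path,events_path File paths for the baseline and event
#'   tables.
#' @return `write_cohort_csv` returns the paths invisibly; `read_cohort_csv`
#'   returns a validated `"aorta_cohort"`. Schema violations are reported
#'   with table name and row numbers.
#' @export
write_cohort_csv <- function(cohort, baseline_path, events_path) {
  stopifnot(inherits(cohort, "aorta_cohort"))
  write_csv_plain(cohort$baseline, baseline_path)
  write_csv_plain(cohort$events, events_path)
  invisible(c(baseline = baseline_path, events = events_path))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(baseline_path, events_path) {
  baseline <- utils::read.csv(baseline_path, stringsAsFactors = FALSE)
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  if (nrow(events) && is.logical(events$diameter_delta_mm)) {
    events$diameter_delta_mm <- as.numeric(events$diameter_delta_mm)
  }
  aorta_cohort(baseline, events)
}

#' Write / read transition matrices as CSV
#'
#' One row per (interval, origin state) with destination-probability columns,
#' so a full non-homogeneous model round-trips through a plain text file.
#' Externally supplied per-interval matrices (e.g. from a published
#' supplement) can be loaded with `read_mcm_csv` and propagated with
#' [propagate_occupancy()].
#'
#' @param model An `"mcm"`.
#' @param path CSV path.
#' @param interval_length Interval length in months used when reading
#'   (default 6).
#' @return `read_mcm_csv` returns a validated `"mcm"`.
#' @export
write_mcm_csv <- function(model, path) {
  stopifnot(inherits(model, "mcm"))
  s <- aorta_states()
  rows <- do.call(rbind, lapply(seq_along(model$matrices), function(k) {
    m <- model$matrices[[k]]
    data.frame(interval = k, origin = s, H = m[, "H"], C = m[, "C"],
               R = m[, "R"], D = m[, "D"])
  }))
  rownames(rows) <- NULL
  write_csv_plain(rows, path)
  invisible(path)
}

#' @rdname write_mcm_csv
#' @export
read_mcm_csv <- function(path, interval_length = 6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("interval", "origin", "H", "C", "R", "D")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("transition-matrix CSV is missing columns: ",
                         paste(miss, collapse = ", "))
  s <- aorta_states()
  intervals <- sort(unique(df$interval))
  if (!identical(intervals, seq_along(intervals))) {
    stop("intervals must be consecutive integers starting at 1")
  }
  mats <- lapply(intervals, function(k) {
    sub <- df[df$interval == k, , drop = FALSE]
    if (!setequal(sub$origin, s) || nrow(sub) != 4L) {
      stop(sprintf("interval %d must have exactly one row per origin state H, C, R, D", k))
    }
    m <- as.matrix(sub[match(s, sub$origin), c("H", "C", "R", "D")])
    dimnames(m) <- list(s, s)
    m
  })
  mcm(mats, interval_length = interval_length)
}

#' Write an occupancy table as CSV
#'
#' Columns: step, months, H, C, R, D, provenance, n, seed.
#' @param occupancy An `"occupancy_table"`.
#' @param path CSV path.
#' @export
write_occupancy_csv <- function(occupancy, path) {
  stopifnot(inherits(occupancy, "occupancy_table"))
  df <- as.data.frame(occupancy)
  df$provenance <- attr(occupancy, "provenance")
  df$n <- attr(occupancy, "n")
  df$seed <- attr(occupancy, "seed")
  write_csv_plain(df, path)
  invisible(path)
}

#' Write a Kaplan-Meier curve as CSV
#'
#' Columns: outcome, stratum, time, n_risk, n_event, n_censor, survival,
#' ci_low, ci_high.
#' @param curve A `"km_curve"`.
#' @param path CSV path.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  df <- as.data.frame(curve)
  df <- cbind(outcome = attr(curve, "outcome_label"),
              stratum = attr(curve, "strata_label") %||% "all", df)
  write_csv_plain(df, path)
  invisible(path)
}

#' Write NNH results as CSV
#'
#' Columns: harm_states, months, absolute_risk, nnh (two decimals, the
#' reporting convention), nnh_ceiling, subgroup, assumption_note.
#' @param result An `"nnh_result"`.
#' @param path CSV path.
#' @export
write_nnh_csv <- function(result, path) {
  stopifnot(inherits(result, "nnh_result"))
  df <- data.frame(
    harm_states = result$harm_states,
    months = result$months,
    absolute_risk = result$absolute_risk,
    nnh = sprintf("%.2f", result$nnh),
    nnh_ceiling = result$nnh_ceiling,
    subgroup = result$subgroup,
    assumption_note = attr(result, "assumption_note")
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a synthetic-cohort configuration from YAML
#'
#' Field names mirror the arguments of [synthetic_config()]; `hazards` may be
#' given as a mapping `approach -> transition -> per-interval list`, e.g.
#' `hazards: {open: {HC: [0.01, ...], ...}, endovascular: {...}}`, or as one
#' flat `transition -> list` mapping applied to both approaches.
#'
#' @param path YAML file path.
#' @return A validated `"synthetic_config"`.
#' @export
read_synthetic_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("n_patients", "seed", "frac_endovascular",
                          "interval_length", "horizon", "censor_prob",
                          "detection"))]
  if (!is.null(raw$frac_abdominal)) {
    args$frac_abdominal <- unlist(raw$frac_abdominal)
  }
  if (!is.null(raw$hazards)) {
    hz <- raw$hazards
    to_matrix <- function(x) do.call(cbind, lapply(x, as.numeric))
    if (all(approach_levels() %in% names(hz))) {
      args$hazards <- lapply(hz[approach_levels()], to_matrix)
    } else {
      args$hazards <- to_matrix(hz)
    }
  }
  do.call(synthetic_config, args)
}
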