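nnh_assumption_note <- function() {
  paste("Worst-case reading: every patient occupying a harm state at the",
        "skipped visit is assumed to go unnoticed and unsalvaged, so the",
        "absolute risk equals the full harm-state occupancy at that visit.")
}

#' Number needed to harm for a skipped surveillance visit
#'
#' The NNH is the reciprocal of the absolute risk that a skipped visit would
#' leave unnoticed. Under the worst-case assumption that every patient in a
#' harm state at the visit goes unnoticed, the absolute risk is the summed
#' occupancy of the chosen harm states at that step.
#'
#' @param occupancy An `"occupancy_table"` (from [propagate_occupancy()],
#'   [simulate_cohort()] or [true_occupancy()]).
#' @param harm_states Non-empty subset of `c("C", "R", "D")` (the healthy
#'   state can never be a harm).
#' @param at_step Step index of the skipped visit (1 = the first scheduled
#'   visit); must exist in the table.
#' @param subgroup Optional label for reporting.
#' @return One-row data frame of class `"nnh_result"`: `subgroup`,
#'   `harm_states`, `at_step`, `months`, `absolute_risk`, `nnh` (unrounded
#'   reciprocal; reported to two decimals by `print` and [write_nnh_csv()])
#'   and `nnh_ceiling` (the smallest whole number of patients who would all
#'   need to skip the visit for one harm to be missed). The worst-case
#'   assumption is attached as attribute `assumption_note`.
#' @details `nnh * absolute_risk` equals 1 exactly before any rounding. A
#'   zero absolute risk raises an explicit "NNH undefined" error rather than
#'   returning infinity.
#' @export
#' @examples
#' m <- diag(4); m[1, ] <- c(0.9525, 0.0258, 0.0167, 0.005)
#' occ <- propagate_occupancy(mcm(list(m)))
#' nnh(occ, harm_states = "R", at_step = 1)
#' nnh(occ, harm_states = c("C", "R"), at_step = 1)
nnh <- function(occupancy, harm_states = c("C", "R"), at_step = 1,
                subgroup = NA_character_) {
  stopifnot(inherits(occupancy, "occupancy_table"))
  harm_states <- unique(harm_states)
  if (length(harm_states) == 0L || !all(harm_states %in% c("C", "R", "D"))) {
    stop("'harm_states' must be a non-empty subset of C, R, D (H is not a harm state)")
  }
  row <- which(occupancy$step == at_step)
  if (length(row) != 1L) {
    stop(sprintf("step %s is not in the occupancy table (steps 0-%d)",
                 format(at_step), max(occupancy$step)))
  }
  risk <- sum(as.numeric(occupancy[row, harm_states, drop = FALSE]))
  if (risk <= 0) {
    stop(sprintf("no harm-state occupancy at step %d: NNH undefined", at_step))
  }
  harm_label <- paste(c("C", "R", "D")[sort(match(harm_states, c("C", "R", "D")))],
                      collapse = "+")
  out <- data.frame(
    subgroup = subgroup,
    harm_states = harm_label,
    at_step = at_step,
    months = occupancy$months[row],
    absolute_risk = risk,
    nnh = 1 / risk,
    nnh_ceiling = ceiling(1 / risk)
  )
  structure(out, assumption_note = nnh_assumption_note(),
            class = c("nnh_result", "data.frame"))
}

#' @export
print.nnh_result <- function(x, ...) {
  cat("Number needed to harm for a skipped surveillance visit\n")
  df <- as.data.frame(x)
  df$absolute_risk <- sprintf("%.2f%%", 100 * df$absolute_risk)
  df$nnh <- sprintf("%.2f", df$nnh)
  print.data.frame(df, row.names = FALSE)
  cat("Assumption:", attr(x, "assumption_note"), "\n")
  invisible(x)
}

#' Compare NNH across labelled subgroup models
#'
#' Propagates each subgroup's transition model from an all-healthy start and
#' computes the NNH at the same visit with the same harm-state set, e.g. to
#' contrast open with endovascular surgery.
#'
#' @param models Named list of `"mcm"` models; names are the subgroup labels
#'   and must be unique and non-empty.
#' @param harm_states,at_step Passed to [nnh()].
#' @param initial Initial distribution for every subgroup (default all
#'   healthy).
#' @return An `"nnh_result"` data frame with one row per subgroup.
#' @export
#' @examples
#' cfg <- synthetic_config(n_patients = 10, seed = 1)
#' models <- list(open = generating_model(cfg, "open"),
#'                endovascular = generating_model(cfg, "endovascular"))
#' compare_subgroup_nnh(models, harm_states = c("C", "R"), at_step = 1)
compare_subgroup_nnh <- function(models, harm_states = c("C", "R"), at_step = 1,
                                 initial = c(1, 0, 0, 0)) {
  if (!is.list(models) || length(models) == 0L) {
    stop("'models' must be a non-empty named list of mcm models")
  }
  labels <- names(models)
  if (is.null(labels) || any(!nzchar(labels)) || anyNA(labels)) {
    stop("every model must carry a non-empty subgroup label")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate subgroup labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  rows <- lapply(labels, function(lab) {
    model <- models[[lab]]
    if (!inherits(model, "mcm")) stop(sprintf("model '%s' is not an mcm", lab))
    occ <- propagate_occupancy(model, initial)
    nnh(occ, harm_states = harm_states, at_step = at_step, subgroup = lab)
  })
  out <- do.call(rbind, rows)
  structure(out, assumption_note = nnh_assumption_note(),
            class = c("nnh_result", "data.frame"))
}
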