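#' Health states of the surveillance model
#'
#' The model tracks four mutually exclusive states after discharge from
#' elective aortic surgery: `H` (healthy: no aortic event, no reintervention,
#' alive), `C` (complication: at least one aortic event — new endoleak,
#' qualifying diameter progression, or new/anastomotic aneurysm — but no
#' reintervention yet), `R` (reintervention received, alive) and `D` (dead,
#' any cause). Severity is ordered H < C < R < D and movement is one-way:
#' H can move to any state, C to R or D, R only to D, and D is absorbing.
#'
#' @return Character vector `c("H", "C", "R", "D")` in severity order.
#' @export
#' @examples
#' aorta_states()
aorta_states <- function() c("H", "C", "R", "D")

# Logical 4x4 matrix of allowed transitions (rows = origin, cols = destination).
allowed_transitions <- function() {
  s <- aorta_states()
  m <- matrix(FALSE, 4, 4, dimnames = list(s, s))
  m["H", ] <- TRUE
  m["C", c("C", "R", "D")] <- TRUE
  m["R", c("R", "D")] <- TRUE
  m["D", "D"] <- TRUE
  m
}

#' Construct a discrete-time non-homogeneous Markov chain model
#'
#' Bundles an ordered sequence of 4x4 row-stochastic transition matrices over
#' the states [aorta_states()], one matrix per follow-up interval. Matrix `k`
#' governs movement across the interval `((k-1) * interval_length,
#' k * interval_length]` months.
#'
#' @param matrices List of 4x4 numeric matrices in state order H, C, R, D.
#' @param interval_length Interval length in months (default 6).
#' @return An object of class `"mcm"`.
#' @details Validity requirements: every row sums to 1 within 1e-12, all
#'   entries lie in \[0, 1\], and structurally forbidden cells (any move that
#'   would decrease severity, e.g. C to H) are exactly zero.
#' @export
#' @examples
#' m <- diag(4)
#' m[1, ] <- c(0.95, 0.03, 0.015, 0.005)
#' mcm(list(m, diag(4)))
mcm <- function(matrices, interval_length = 6) {
  if (!is.list(matrices) || length(matrices) < 1L) {
    stop("'matrices' must be a non-empty list of 4x4 transition matrices")
  }
  if (!is.numeric(interval_length) || length(interval_length) != 1L ||
      interval_length <= 0) {
    stop("'interval_length' must be a single positive number of months")
  }
  s <- aorta_states()
  ok <- allowed_transitions()
  matrices <- lapply(seq_along(matrices), function(k) {
    m <- matrices[[k]]
    if (!is.matrix(m) || !identical(dim(m), c(4L, 4L)) || !is.numeric(m)) {
      stop(sprintf("matrix %d is not a numeric 4x4 matrix", k))
    }
    dimnames(m) <- list(s, s)
    if (any(m < 0 | m > 1)) {
      stop(sprintf("matrix %d has entries outside [0, 1]", k))
    }
    if (any(m[!ok] != 0)) {
      stop(sprintf(
        "matrix %d has non-zero probability on a forbidden transition (no recovery, D absorbing)",
        k
      ))
    }
    if (any(abs(rowSums(m) - 1) > 1e-12)) {
      stop(sprintf("matrix %d is not row-stochastic (rows must sum to 1)", k))
    }
    m
  })
  structure(
    list(matrices = matrices, interval_length = interval_length,
         states = s),
    class = "mcm"
  )
}

#' @export
print.mcm <- function(x, ...) {
  k <- length(x$matrices)
  cat(sprintf(
    "Discrete-time non-homogeneous Markov chain: %d interval%s of %g months (horizon %g months)\n",
    k, if (k == 1L) "" else "s", x$interval_length, k * x$interval_length
  ))
  cat("States: H (healthy) > C (complication) > R (reintervention) > D (death); D absorbing\n")
  for (i in seq_len(min(k, 2L))) {
    cat(sprintf("\nInterval %d (%g-%g months):\n", i,
                (i - 1) * x$interval_length, i * x$interval_length))
    print(round(x$matrices[[i]], 4))
  }
  if (k > 2L) cat(sprintf("\n... and %d further interval matrices\n", k - 2L))
  invisible(x)
}

#' Number of follow-up intervals in a model
#' @param model An `"mcm"` object.
#' @return Integer count of interval matrices.
#' @export
n_intervals <- function(model) {
  stopifnot(inherits(model, "mcm"))
  length(model$matrices)
}

# Internal constructor for occupancy tables shared by propagation, simulation
# and the synthetic-cohort oracle. `occ` is a (K+1) x 4 matrix, row 0 first.
new_occupancy_table <- function(occ, interval_length, provenance,
                                n = NA_integer_, seed = NA_integer_) {
  stopifnot(is.matrix(occ), ncol(occ) == 4L)
  provenance <- match.arg(provenance, c("exact", "simulated"))
  steps <- seq_len(nrow(occ)) - 1L
  out <- data.frame(
    step = steps,
    months = steps * interval_length,
    H = occ[, 1L], C = occ[, 2L], R = occ[, 3L], D = occ[, 4L]
  )
  rownames(out) <- NULL
  structure(out,
            interval_length = interval_length,
            provenance = provenance,
            n = n, seed = seed,
            class = c("occupancy_table", "data.frame"))
}

#' @export
print.occupancy_table <- function(x, digits = 4, ...) {
  prov <- attr(x, "provenance")
  hdr <- if (identical(prov, "simulated")) {
    sprintf("State occupancy (simulated relative frequencies, n = %d, seed = %d)",
            attr(x, "n"), attr(x, "seed"))
  } else {
    "State occupancy (exact propagation)"
  }
  cat(hdr, "\n")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

# Validate an occupancy table against its structural invariants; used in
# tests and defensive checks. Tolerance 1e-9 for exact tables.
check_occupancy <- function(occ) {
  stopifnot(inherits(occ, "occupancy_table"))
  m <- as.matrix(occ[, c("H", "C", "R", "D")])
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("occupancy rows must sum to 1")
  }
  if (any(diff(m[, "D"]) < -1e-12)) stop("death occupancy must be non-decreasing")
  if (any(diff(m[, "H"]) > 1e-12)) stop("healthy occupancy must be non-increasing")
  invisible(occ)
}
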