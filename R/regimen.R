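#' Dosing regimens
#'
#' A dosing regimen is the finite truncation of a schedule
#' \code{{(tau_n, d_n)}}: dose \code{d_n} is administered at time
#' \code{t_{n-1} = tau_1 + ... + tau_{n-1}} (first dose at \code{t = 0}),
#' and cycle \code{n} is the half-open interval \code{[t_{n-1}, t_n)}.
#' Evaluation beyond the last cycle boundary \code{t_N} is a domain error
#' rather than extrapolation; append a trailing zero dose to model washout.
#'
#' Doses are amounts (e.g. mg) for oral and finite-absorption-time models;
#' for intravenous bolus dosing the same structure carries concentration
#' increments (e.g. mg/mL) — see \code{\link{bolus_concentration}}.
#'
#' @param doses numeric vector of nonnegative dose amounts \code{d_n}.
#'   Zero doses are legal and encode skipped intakes.
#' @param intervals numeric vector of positive inter-dose intervals
#'   \code{tau_n}, same length as \code{doses}. \code{tau_n} is the time
#'   from dose \code{n} to dose \code{n+1} (the last one closes the
#'   schedule at \code{t_N}).
#' @return An object of class \code{"dose_regimen"}.
#' @examples
#' dose_regimen(doses = c(600, 600, 700, 500, 400, 300),
#'              intervals = c(4, 4, 8, 4, 6, 4))
#' @export
dose_regimen <- function(doses, intervals) {
  if (!is.numeric(doses) || !is.numeric(intervals))
    stop("`doses` and `intervals` must be numeric", call. = FALSE)
  if (length(doses) != length(intervals))
    stop("`doses` and `intervals` must have the same length", call. = FALSE)
  if (length(doses) < 1L)
    stop("a regimen needs at least one dose", call. = FALSE)
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("all doses must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all intervals must be finite and > 0", call. = FALSE)
  doses <- as.numeric(doses)
  intervals <- as.numeric(intervals)
  times <- c(0, cumsum(intervals))
  equi <- length(doses) == 1L ||
    (diff(range(doses)) == 0 && diff(range(intervals)) == 0)
  structure(
    list(doses = doses, intervals = intervals, times = times,
         n = length(doses), equi = equi),
    class = "dose_regimen")
}

#' Equi-dose regimen constructor
#'
#' Constant dose \code{d} every \code{tau} time units for \code{n_doses}
#' administrations, the "equi-dosing" schedule for which the closed-form
#' per-cycle metrics and steady-state asymptotics are available.
#'
#' @param d dose amount, >= 0.
#' @param tau dosing interval, > 0.
#' @param n_doses number of doses, >= 1.
#' @return A \code{\link{dose_regimen}} with \code{t_n = n*tau}.
#' @examples
#' equidose_regimen(d = 250, tau = 4, n_doses = 6)
#' @export
equidose_regimen <- function(d, tau, n_doses) {
  if (!is.numeric(n_doses) || length(n_doses) != 1L || n_doses < 1 ||
      n_doses != round(n_doses))
    stop("`n_doses` must be a positive integer", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0)
    stop("`d` must be a single finite nonnegative number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single finite positive number", call. = FALSE)
  dose_regimen(rep(d, n_doses), rep(tau, n_doses))
}

#' Finite-absorption-time regimen
#'
#' Augments a \code{\link{dose_regimen}} with per-dose absorption cutoffs
#' \code{s_n}: absorption (the assimilation phase) runs on
#' \code{[t_{n-1}, s_n]} and only elimination (the clearance phase) on
#' \code{[s_n, t_n]}. \code{s_n = t_n} is legal (absorption for the whole
#' cycle, a degenerate clearance phase); \code{s_n <= t_{n-1}} is not.
#'
#' @param regimen a \code{\link{dose_regimen}}.
#' @param fat per-cycle finite-absorption-time durations
#'   \code{sigma_n = s_n - t_{n-1}}, a scalar (recycled) or a vector of
#'   length \code{n_doses}; each must satisfy \code{0 < sigma_n <= tau_n}.
#' @return An object of class \code{c("fat_regimen", "dose_regimen")} with
#'   absolute cutoffs \code{$cutoffs} and durations \code{$fat}.
#' @examples
#' fat_regimen(equidose_regimen(600, 5, 8), fat = 2)
#' @export
fat_regimen <- function(regimen, fat) {
  .check_regimen(regimen)
  if (!is.numeric(fat) || any(!is.finite(fat)))
    stop("`fat` must be numeric and finite", call. = FALSE)
  if (length(fat) == 1L) fat <- rep(as.numeric(fat), regimen$n)
  if (length(fat) != regimen$n)
    stop("`fat` must be a scalar or have one entry per dose", call. = FALSE)
  if (any(fat <= 0) || any(fat > regimen$intervals))
    stop("each absorption duration must satisfy 0 < sigma_n <= tau_n",
         call. = FALSE)
  regimen$fat <- as.numeric(fat)
  regimen$cutoffs <- regimen$times[seq_len(regimen$n)] + regimen$fat
  class(regimen) <- c("fat_regimen", "dose_regimen")
  regimen
}

#' Dose administration times
#'
#' @param regimen a \code{\link{dose_regimen}}.
#' @return The strictly increasing cycle boundaries
#'   \code{(t_0 = 0, t_1, ..., t_N)}; dose \code{n} is given at
#'   \code{t_{n-1}}.
#' @export
dose_times <- function(regimen) {
  .check_regimen(regimen)
  regimen$times
}

#' Number of doses in a regimen
#' @param regimen a \code{\link{dose_regimen}}.
#' @return Integer count \code{N}.
#' @export
n_doses <- function(regimen) {
  .check_regimen(regimen)
  regimen$n
}

#' Locate the dosing cycle containing a time point
#'
#' Cycles are half-open \code{[t_{n-1}, t_n)}: a dose instant opens the new
#' cycle (the absorbed amount \code{y} is right-continuous there). The end
#' of the schedule \code{t = t_N} maps to cycle \code{N} with offset
#' \code{tau_N}. Lookup is a binary search (\code{findInterval}) over the
#' cycle boundaries.
#'
#' @param regimen a \code{\link{dose_regimen}}.
#' @param t numeric vector of times in \code{[0, t_N]}.
#' @return A list with integer \code{cycle} and numeric \code{offset}
#'   (\code{t - t_{n-1}}), each the length of \code{t}.
#' @export
cycle_of <- function(regimen, t) {
  .check_regimen(regimen)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be numeric and finite", call. = FALSE)
  tn <- regimen$times
  if (any(t < 0) || any(t > tn[length(tn)]))
    stop("`t` outside the dosing schedule [0, ", tn[length(tn)], "]",
         call. = FALSE)
  cyc <- findInterval(t, tn, rightmost.closed = TRUE)
  list(cycle = cyc, offset = t - tn[cyc])
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("Dosing regimen: %d dose%s over [0, %g]%s\n", x$n,
              if (x$n > 1) "s" else "", x$times[x$n + 1L],
              if (x$equi) " (equi-dose)" else ""))
  cat("  doses:     ", paste(format(x$doses), collapse = ", "), "\n")
  cat("  intervals: ", paste(format(x$intervals), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.fat_regimen <- function(x, ...) {
  NextMethod()
  cat("  F.A.T.:    ", paste(format(x$fat), collapse = ", "), "\n")
  invisible(x)
}

.check_regimen <- function(regimen) {
  if (!inherits(regimen, "dose_regimen"))
    stop("`regimen` must be a dose_regimen object", call. = FALSE)
  invisible(regimen)
}

.check_fat_regimen <- function(regimen) {
  if (!inherits(regimen, "fat_regimen"))
    stop("`regimen` must be a fat_regimen object (see fat_regimen())",
         call. = FALSE)
  invisible(regimen)
}
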