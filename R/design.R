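# Regimen design: invert the steady-state envelope. Both envelope bounds
# are linear in the dose d, so their ratio depends on tau alone; a target
# envelope (lower*, upper*) is met by solving the monotone scalar equation
# ratio(tau) = upper*/lower* for tau, then scaling d linearly.

#' Steady-state peak/trough ratio
#'
#' \code{ss_upper/ss_lower} for a unit dose — independent of \code{d}
#' because both bounds are linear in it. Always > 1, tends to 1 as the
#' dosing interval shrinks (the limit cycle flattens) and grows without
#' bound as the interval lengthens (troughs vanish), which makes it a
#' monotone handle for root-finding.
#'
#' @param params \code{\link{pk_parameters}}.
#' @param tau dosing interval, > 0 (may be a vector).
#' @return Dimensionless ratio per entry of \code{tau}.
#' @export
steady_state_ratio <- function(params, tau) {
  .check_params(params)
  vapply(tau, function(tt) {
    b <- steady_state_bounds(params, 1, tt)
    unname(b["ss_upper"] / b["ss_lower"])
  }, numeric(1))
}

#' Design an equi-dose regimen from steady-state targets
#'
#' Finds \code{(d*, tau*)} whose asymptotic concentration envelope equals
#' the prescribed \code{(ss_lower*, ss_upper*)}. The interval is found by
#' bracketed root-finding on \code{steady_state_ratio(tau) = upper*/lower*}
#' (bracket expanded geometrically inside \code{[1e-6, 1e6]} time units,
#' monotonicity checked on the bracket), then the dose follows by
#' linearity: \code{d* = lower* / ss_lower(d = 1, tau*)}.
#'
#' @param params \code{\link{pk_parameters}}.
#' @param ss_lower_target,ss_upper_target prescribed envelope, with
#'   \code{0 < ss_lower_target < ss_upper_target}.
#' @return List with \code{d}, \code{tau} and the achieved
#'   \code{ss_lower}, \code{ss_upper}.
#' @examples
#' p <- pk_parameters(0.42, 0.4, 0.00449)
#' tgt <- steady_state_bounds(p, 600, 5)
#' design_regimen(p, tgt["ss_lower"], tgt["ss_upper"])
#' @export
design_regimen <- function(params, ss_lower_target, ss_upper_target) {
  .check_params(params)
  lo <- as.numeric(ss_lower_target); up <- as.numeric(ss_upper_target)
  if (!is.finite(lo) || !is.finite(up) || lo <= 0 || up <= lo)
    stop("infeasible target: need 0 < ss_lower_target < ss_upper_target ",
         "(the steady-state envelope always has positive width)",
         call. = FALSE)
  target <- up / lo
  f <- function(tt) steady_state_ratio(params, tt) - target
  # geometric bracket expansion around tau = 1
  lower <- 1; upper <- 1
  while (f(lower) > 0 && lower > 1e-6) lower <- lower / 4
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 4
  lower <- max(lower, 1e-6); upper <- min(upper, 1e6)
  flo <- f(lower); fup <- f(upper)
  if (flo > 0 || fup < 0)
    stop("design_regimen: target ratio ", format(target),
         " not bracketed for tau in [1e-6, 1e6]; f(lower) = ", format(flo),
         ", f(upper) = ", format(fup), call. = FALSE)
  # monotonicity sanity on the bracket before trusting the root
  grid <- exp(seq(log(lower), log(upper), length.out = 9))
  if (any(diff(steady_state_ratio(params, grid)) <= 0))
    stop("design_regimen: steady-state ratio is not strictly increasing ",
         "on the search bracket; refusing to return a root", call. = FALSE)
  tau_star <- uniroot(f, c(lower, upper), tol = .Machine$double.eps,
                      maxiter = 2000L)$root
  d_star <- lo / unname(steady_state_bounds(params, 1, tau_star)["ss_lower"])
  achieved <- steady_state_bounds(params, d_star, tau_star)
  list(d = d_star, tau = tau_star,
       ss_lower = unname(achieved["ss_lower"]),
       ss_upper = unname(achieved["ss_upper"]))
}

#' Is an equi-dose schedule effective?
#'
#' Membership test for the effective-dosage set: the schedule's asymptotic
#' envelope must sit inside the prescribed window, i.e.
#' \code{ss_lower >= mic} (efficacy floor, minimum inhibitory
#' concentration) and \code{ss_upper <= tc} (safety ceiling, toxic
#' concentration).
#'
#' @param params \code{\link{pk_parameters}}.
#' @param d dose amount.
#' @param tau dosing interval.
#' @param mic minimum inhibitory concentration, > 0.
#' @param tc toxic concentration, > mic.
#' @param tol relative slack on the window edges, so that a regimen
#'   designed to sit exactly on the boundary is not rejected for the last
#'   unit in the last place.
#' @return Logical scalar.
#' @export
is_effective <- function(params, d, tau, mic, tc, tol = 1e-9) {
  if (!is.numeric(mic) || !is.numeric(tc) || mic <= 0 || tc <= mic)
    stop("need 0 < mic < tc", call. = FALSE)
  b <- steady_state_bounds(params, d, tau)
  unname(b["ss_lower"] >= mic * (1 - tol) && b["ss_upper"] <= tc * (1 + tol))
}
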