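# Independent numerical verification of the closed forms: the impulsive
# ODE systems are integrated with an adaptive solver restarted at every
# dose instant (and absorption cutoff), with the jump applied to the
# state. No closed-form solution and no matrix-exponential stepping is
# used here, so agreement with the analytic trajectories is a genuine
# cross-check, not a tautology.

#' Numerically integrate a multi-dose impulsive ODE system
#'
#' Integrates the model equations with \code{deSolve::lsoda} segment by
#' segment between events. For \code{model = "oral"} the state is
#' \code{(y, x)} with \code{y' = -ka y}, \code{x' = ka gamma y - ke x} and
#' \code{y} jumping up by \code{d_n} at each dose instant. For
#' \code{"bolus"} the state is \code{x} with \code{x' = -ke x} and
#' \code{x} jumping by the dose. For \code{"pbftpk"} the oral system runs
#' with \code{y} reset to \code{d_n} at dose instants and to 0 at each
#' absorption cutoff \code{s_n} (a \code{\link{fat_regimen}} is required).
#'
#' @param params \code{\link{pk_parameters}} (for \code{"bolus"} a bare
#'   numeric \code{ke} is also accepted).
#' @param regimen \code{\link{dose_regimen}} (\code{\link{fat_regimen}}
#'   for \code{"pbftpk"}).
#' @param t_grid sorted times within \code{[0, t_N]} at which to sample
#'   the trajectory. Samples at event times take the post-jump
#'   (right-continuous) state.
#' @param model one of \code{"oral"}, \code{"bolus"}, \code{"pbftpk"}.
#' @param tol relative and absolute integration tolerance, in
#'   \code{[1e-13, 1e-6]}.
#' @return A \code{"concentration_profile"} data frame with columns
#'   \code{t}, \code{x}, \code{cycle} and (except bolus) \code{y}.
#' @export
integrate_multidose <- function(params, regimen,
                                t_grid,
                                model = c("oral", "bolus", "pbftpk"),
                                tol = 1e-12) {
  model <- match.arg(model)
  .check_regimen(regimen)
  if (!is.numeric(tol) || length(tol) != 1L || tol < 1e-13 || tol > 1e-6)
    stop("`tol` must lie in [1e-13, 1e-6]", call. = FALSE)
  .check_grid(t_grid, regimen)
  tN <- regimen$times[regimen$n + 1L]
  if (length(t_grid) && (min(t_grid) < 0 || max(t_grid) > tN))
    stop("`t_grid` outside the dosing schedule", call. = FALSE)

  if (model == "bolus") {
    ke <- if (inherits(params, "pk_parameters")) params$ke else params
    .check_ke(ke)
    rhs <- function(t, state, p) list(-ke * state)
    state <- 0
    events <- data.frame(time = regimen$times[seq_len(regimen$n)],
                         var = "y1", jump = regimen$doses,
                         reset = FALSE)
    dim_names <- "x"
  } else {
    .check_params(params)
    ka <- params$ka; ke <- params$ke; gamma <- params$gamma
    rhs <- function(t, state, p) {
      list(c(-ka * state[1], ka * gamma * state[1] - ke * state[2]))
    }
    state <- c(0, 0)
    if (model == "pbftpk") {
      .check_fat_regimen(regimen)
      # cutoffs sort before doses at coincident times (sigma_n = tau_n):
      # absorption of dose n ends just as dose n+1 arrives
      events <- rbind(
        data.frame(time = regimen$cutoffs, var = "y1", jump = 0,
                   reset = TRUE, prio = 0),
        data.frame(time = regimen$times[seq_len(regimen$n)], var = "y1",
                   jump = regimen$doses, reset = TRUE, prio = 1))
      events <- events[order(events$time, events$prio), , drop = FALSE]
    } else {
      events <- data.frame(time = regimen$times[seq_len(regimen$n)],
                           var = "y1", jump = regimen$doses,
                           reset = FALSE)
    }
    dim_names <- c("y", "x")
  }

  boundaries <- unique(c(0, events$time, tN))
  boundaries <- sort(boundaries)
  seg_idx <- if (length(t_grid))
    findInterval(t_grid, boundaries, rightmost.closed = TRUE)
  else integer(0)

  out_state <- matrix(NA_real_, nrow = length(t_grid),
                      ncol = length(state))
  for (i in seq_len(length(boundaries) - 1L)) {
    a <- boundaries[i]; b <- boundaries[i + 1L]
    ev <- which(events$time == a)
    for (j in ev) {
      if (events$reset[j]) state[1] <- events$jump[j]
      else state[1] <- state[1] + events$jump[j]
    }
    want <- which(seg_idx == i)
    at_a <- want[t_grid[want] == a]
    if (length(at_a)) out_state[at_a, ] <- rep(state, each = length(at_a))
    interior <- want[t_grid[want] > a]
    times <- unique(c(a, t_grid[interior], b))
    sol <- deSolve::lsoda(y = state, times = times, func = rhs,
                          parms = NULL, rtol = tol, atol = tol,
                          maxsteps = 100000L)
    if (nrow(sol) != length(times) || any(!is.finite(sol)))
      stop("integrator failed on segment [", a, ", ", b, "]",
           call. = FALSE)
    if (length(interior)) {
      rows <- match(t_grid[interior], times)
      out_state[interior, ] <- sol[rows, -1, drop = FALSE]
    }
    state <- as.numeric(sol[nrow(sol), -1])
  }
  # trailing events exactly at tN (e.g. a cutoff at the schedule end)
  ev <- which(events$time == tN)
  for (j in ev) {
    if (events$reset[j]) state[1] <- events$jump[j]
    else state[1] <- state[1] + events$jump[j]
    at_end <- which(seg_idx > 0 & t_grid == tN)
    if (length(at_end)) out_state[at_end, ] <- rep(state, each = length(at_end))
  }

  cyc <- if (length(t_grid)) cycle_of(regimen, t_grid)$cycle else integer(0)
  out <- if (model == "bolus") {
    data.frame(t = t_grid, x = out_state[, 1], cycle = cyc)
  } else {
    data.frame(t = t_grid, x = out_state[, 2], y = out_state[, 1],
               cycle = cyc)
  }
  class(out) <- c("concentration_profile", "data.frame")
  out
}

#' Adaptive quadrature of a concentration curve
#'
#' Thin wrapper over \code{stats::integrate} with a pure relative error
#' target, used to cross-check the closed-form AUC expressions.
#'
#' @param f vectorized function of time.
#' @param a,b integration limits, \code{a < b}.
#' @param tol relative error tolerance.
#' @return The integral value.
#' @export
auc_numeric <- function(f, a, b, tol = 1e-10) {
  if (!is.function(f)) stop("`f` must be a function", call. = FALSE)
  if (!(a < b)) stop("need a < b", call. = FALSE)
  fv <- f(c(a, b))
  if (any(!is.finite(fv)))
    stop("curve evaluates non-finite at the integration limits",
         call. = FALSE)
  res <- stats::integrate(f, a, b, rel.tol = tol, abs.tol = 0,
                          subdivisions = 1000L, stop.on.error = TRUE)
  res$value
}
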