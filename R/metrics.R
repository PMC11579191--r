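# Per-cycle and asymptotic metrics for the equi-dose multiple-dose Bateman
# model. All closed forms below are specific to constant (d, tau); general
# regimens are served numerically via auc_numeric()/integrate_multidose().

# internal: equi-dose building blocks
.equi <- function(params, tau) {
  list(alpha = exp(-params$ka * tau), beta = exp(-params$ke * tau),
       k = .k_scale(params))
}

.check_equi_inputs <- function(params, d, tau) {
  .check_params(params)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0)
    stop("`d` must be a single finite nonnegative number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single finite positive number", call. = FALSE)
}

# internal: equi-dose cycle coefficients C1(n), C2(n) without a regimen
.equi_coef <- function(params, d, tau, n) {
  e <- .equi(params, tau)
  list(C1 = e$k * d * (1 - e$beta^n) / (1 - e$beta),
       C2 = e$k * d * (1 - e$alpha^n) / (1 - e$alpha))
}

#' Area under the curve for one dosing cycle
#'
#' Closed-form AUC of the equi-dose concentration over cycle
#' \code{n}, \code{[(n-1)tau, n tau]}:
#' \code{k d [(1 - beta^n)/ke - (1 - alpha^n)/ka]} with
#' \code{k = ka*gamma/(ka-ke)}, \code{alpha = exp(-ka tau)},
#' \code{beta = exp(-ke tau)}. Increases with \code{n} toward the
#' single-dose total AUC (\code{\link{auc_single_infinite}}).
#'
#' @param params \code{\link{pk_parameters}}.
#' @param d dose amount.
#' @param tau dosing interval.
#' @param n cycle index, >= 1 (may be a vector).
#' @return AUC (concentration x time) per entry of \code{n}.
#' @export
auc_cycle <- function(params, d, tau, n) {
  .check_equi_inputs(params, d, tau)
  if (any(n < 1) || any(n != round(n)))
    stop("`n` must be integer >= 1", call. = FALSE)
  e <- .equi(params, tau)
  e$k * d * ((1 - e$beta^n) / params$ke - (1 - e$alpha^n) / params$ka)
}

#' Total single-dose area under the curve
#'
#' AUC of the single-dose Bateman curve over \code{[0, Inf)}:
#' \code{k d (1/ke - 1/ka)}, which simplifies to \code{gamma d / ke} — the
#' absorption rate drops out. Equal to the per-cycle AUC of the limiting
#' steady-state cycle for any dosing interval.
#'
#' @inheritParams auc_cycle
#' @return AUC (concentration x time).
#' @export
auc_single_infinite <- function(params, d) {
  .check_params(params)
  if (d < 0) stop("`d` must be >= 0", call. = FALSE)
  .k_scale(params) * d * (1 / params$ke - 1 / params$ka)
}

#' Peak time within a dosing cycle
#'
#' The interior critical point of the cycle-\code{n} concentration is at
#' offset \code{log(ka C2 / (ke C1)) / (ka - ke)} past the cycle start.
#' For short intervals the printed critical point can fall beyond
#' \code{tau}; the function then returns the in-cycle argmax (the cycle
#' endpoint) and warns that the interior point was clipped.
#'
#' @inheritParams auc_cycle
#' @param n single cycle index >= 1.
#' @return Absolute peak time \code{(n-1)tau + offset}.
#' @export
t_max_cycle <- function(params, d, tau, n) {
  .check_equi_inputs(params, d, tau)
  cf <- .equi_coef(params, d, tau, n)
  off <- log(params$ka * cf$C2 / (params$ke * cf$C1)) /
    (params$ka - params$ke)
  if (!is.finite(off) || off < 0 || off > tau) {
    # compare endpoint values; interior point is outside the cycle
    xs <- function(s) cf$C1 * exp(-params$ke * s) - cf$C2 * exp(-params$ka * s)
    off_clip <- if (xs(0) >= xs(tau)) 0 else tau
    warning("interior critical point at offset ", format(off),
            " lies outside [0, tau]; returning the boundary argmax",
            call. = FALSE)
    off <- off_clip
  }
  (n - 1) * tau + off
}

#' Peak concentration within a dosing cycle
#'
#' Evaluates the closed power form
#' \code{C1 r^{-ke/(ka-ke)} - C2 r^{-ka/(ka-ke)}} with
#' \code{r = ka C2 / (ke C1)}, i.e. the cycle concentration at its
#' interior critical point; identical to evaluating the trajectory at
#' \code{\link{t_max_cycle}}. When the critical point is clipped to the
#' cycle boundary the boundary value is returned instead.
#'
#' @inheritParams t_max_cycle
#' @return Peak concentration in cycle \code{n}; increases with \code{n}
#'   toward the steady-state upper bound.
#' @export
x_max_cycle <- function(params, d, tau, n) {
  .check_equi_inputs(params, d, tau)
  if (d == 0) return(0)
  cf <- .equi_coef(params, d, tau, n)
  r <- params$ka * cf$C2 / (params$ke * cf$C1)
  off <- log(r) / (params$ka - params$ke)
  if (is.finite(off) && off >= 0 && off <= tau) {
    ex <- 1 / (params$ka - params$ke)
    cf$C1 * r^(-params$ke * ex) - cf$C2 * r^(-params$ka * ex)
  } else {
    s <- if (off < 0) 0 else tau
    cf$C1 * exp(-params$ke * s) - cf$C2 * exp(-params$ka * s)
  }
}

#' Cycle-end trough concentration (remainder)
#'
#' The concentration left in circulation at the end of cycle \code{n},
#' \code{x(n tau) = k d [beta (1-beta^n)/(1-beta) - alpha (1-alpha^n)/(1-alpha)]}.
#' Strictly positive for every \code{n} in both ordinary and flip-flop
#' kinetics, and increasing toward the steady-state lower bound.
#'
#' @inheritParams auc_cycle
#' @return Trough concentration per entry of \code{n}.
#' @export
remainder <- function(params, d, tau, n) {
  .check_equi_inputs(params, d, tau)
  if (any(n < 1) || any(n != round(n)))
    stop("`n` must be integer >= 1", call. = FALSE)
  e <- .equi(params, tau)
  e$k * d * (e$beta * (1 - e$beta^n) / (1 - e$beta) -
             e$alpha * (1 - e$alpha^n) / (1 - e$alpha))
}

#' Steady-state concentration envelope
#'
#' Limits of the cycle troughs and peaks as the number of doses grows:
#' the lower bound is \code{k d [beta/(1-beta) - alpha/(1-alpha)]} and the
#' upper bound is
#' \code{k d [(1/(1-beta)) R^{-ke/(ka-ke)} - (1/(1-alpha)) R^{-ka/(ka-ke)}]}
#' with \code{R = ka (1-beta) / (ke (1-alpha))}. Both are linear in
#' \code{d}, increase as \code{tau} shrinks, and satisfy
#' \code{upper > lower > 0} for \code{d > 0}.
#'
#' @inheritParams auc_cycle
#' @return Named numeric vector \code{c(ss_lower=, ss_upper=)}.
#' @export
steady_state_bounds <- function(params, d, tau) {
  .check_equi_inputs(params, d, tau)
  e <- .equi(params, tau)
  lower <- e$k * d * (e$beta / (1 - e$beta) - e$alpha / (1 - e$alpha))
  R <- params$ka * (1 - e$beta) / (params$ke * (1 - e$alpha))
  ex <- 1 / (params$ka - params$ke)
  upper <- e$k * d * (R^(-params$ke * ex) / (1 - e$beta) -
                      R^(-params$ka * ex) / (1 - e$alpha))
  c(ss_lower = lower, ss_upper = upper)
}

#' Width of the asymptotic therapeutic range
#'
#' \code{ss_upper - ss_lower}: the spread of concentrations in the limit
#' cycle. Increases with both \code{d} and \code{tau}; as \code{tau} grows
#' it approaches the single-dose peak concentration (the trough limit is
#' zero). Note this "therapeutic range" is the model's asymptotic
#' concentration envelope, not a clinical MIC/TC window.
#'
#' @inheritParams auc_cycle
#' @return Width (concentration).
#' @export
therapeutic_width <- function(params, d, tau) {
  b <- steady_state_bounds(params, d, tau)
  unname(b["ss_upper"] - b["ss_lower"])
}

#' Sup-norm gap between successive cycles
#'
#' \code{sup_{t in I_n} |x^{(n)}(t) - x^{(n-1)}(t - tau)|}, the measure of
#' how far the trajectory still is from its limit cycle. In the equi-dose
#' model the difference of the two cycles is the two-exponential function
#' \code{dC1 e^{-ke s} - dC2 e^{-ka s}} on \code{s in [0, tau]} with
#' \code{dC1 = k d beta^{n-1}}, \code{dC2 = k d alpha^{n-1}}; its supremum
#' is located in closed form among the endpoints and the unique interior
#' critical point. Gaps decay geometrically with ratio
#' \code{max(alpha, beta)}.
#'
#' @inheritParams auc_cycle
#' @param n cycle index >= 2 (may be a vector).
#' @return The sup-norm gap per entry of \code{n}.
#' @export
periodicity_gap <- function(params, d, tau, n) {
  .check_equi_inputs(params, d, tau)
  if (any(n < 2) || any(n != round(n)))
    stop("`n` must be integer >= 2 (gap compares cycle n with n-1)",
         call. = FALSE)
  e <- .equi(params, tau)
  vapply(n, function(m) {
    dC1 <- e$k * d * e$beta^(m - 1)
    dC2 <- e$k * d * e$alpha^(m - 1)
    .sup_two_exp(dC1, dC2, params$ka, params$ke, tau)
  }, numeric(1))
}

# internal: sup over [0, tau] of |a e^{-ke s} - b e^{-ka s}|
.sup_two_exp <- function(a, b, ka, ke, tau) {
  f <- function(s) abs(a * exp(-ke * s) - b * exp(-ka * s))
  cand <- c(0, tau)
  arg <- ka * b / (ke * a)
  if (is.finite(arg) && arg > 0) {
    s_star <- log(arg) / (ka - ke)
    if (is.finite(s_star) && s_star > 0 && s_star < tau)
      cand <- c(cand, s_star)
  }
  max(f(cand))
}

#' First cycle of the epsilon-steady-state
#'
#' The smallest \code{n} such that every later successive-cycle sup-gap
#' stays below \code{eps}. The infinite tail quantifier is certified by
#' the geometric envelope \code{gap(m) <= k d (beta^{m-1} + alpha^{m-1})},
#' which is decreasing: gaps are scanned explicitly until the envelope
#' itself drops below \code{eps}, so no later gap can resurface.
#'
#' @inheritParams auc_cycle
#' @param eps gap tolerance, > 0.
#' @return Integer cycle index (>= 2); halving \code{eps} never decreases it.
#' @export
n_epsilon <- function(params, d, tau, eps) {
  .check_equi_inputs(params, d, tau)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a single positive number", call. = FALSE)
  if (d == 0) return(2L)
  e <- .equi(params, tau)
  first_ok <- NA_integer_
  m <- 2L
  repeat {
    g <- periodicity_gap(params, d, tau, m)
    if (g < eps) {
      if (is.na(first_ok)) first_ok <- m
    } else first_ok <- NA_integer_
    envelope <- e$k * d * (e$beta^(m - 1) + e$alpha^(m - 1))
    if (!is.na(first_ok) && envelope < eps) return(first_ok)
    m <- m + 1L
    if (m > 1e6L)
      stop("n_epsilon: no certified index below 1e6 cycles", call. = FALSE)
  }
}

#' Steady-state summary for an equi-dose schedule
#'
#' Bundles the asymptotic envelope, its width, the limiting per-cycle AUC
#' (equal to the single-dose total AUC), the epsilon-steady-state index
#' and the periodicity gaps up to that index.
#'
#' @inheritParams n_epsilon
#' @return An object of class \code{"steady_state_summary"}: list with
#'   \code{ss_lower}, \code{ss_upper}, \code{width}, \code{auc_ss},
#'   \code{eps}, \code{n_eps}, \code{gaps}.
#' @export
steady_state_summary <- function(params, d, tau, eps = 1e-6) {
  .check_equi_inputs(params, d, tau)
  if (d == 0)
    stop("degenerate zero-dose regimen: all concentrations are ",
         "identically zero and the steady-state envelope has width 0",
         call. = FALSE)
  b <- steady_state_bounds(params, d, tau)
  n_eps <- n_epsilon(params, d, tau, eps)
  # limiting per-cycle AUC: alpha^n, beta^n -> 0 in the cycle AUC formula
  auc_ss <- .k_scale(params) * d * (1 / params$ke - 1 / params$ka)
  structure(
    list(ss_lower = unname(b["ss_lower"]), ss_upper = unname(b["ss_upper"]),
         width = unname(b["ss_upper"] - b["ss_lower"]), auc_ss = auc_ss,
         eps = eps, n_eps = n_eps,
         gaps = periodicity_gap(params, d, tau, 2:max(2L, n_eps))),
    class = "steady_state_summary")
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat("Steady-state summary (equi-dose)\n")
  cat(sprintf("  envelope: [%g, %g]  width %g\n",
              x$ss_lower, x$ss_upper, x$width))
  cat(sprintf("  per-cycle AUC at steady state: %g\n", x$auc_ss))
  cat(sprintf("  eps-steady state (eps = %g) from cycle %d\n",
              x$eps, x$n_eps))
  invisible(x)
}
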