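#' Single-dose Bateman concentration
#'
#' Plasma concentration after one oral dose under first-order absorption
#' and elimination:
#' \code{x(t) = k d (exp(-ke t) - exp(-ka t))} with
#' \code{k = ka*gamma/(ka - ke)}. Nonnegative for all \code{t >= 0}
#' whichever of \code{ka}, \code{ke} is larger.
#'
#' @param params \code{\link{pk_parameters}}.
#' @param d dose amount, >= 0.
#' @param t numeric vector of times, >= 0.
#' @return Concentration at each \code{t}.
#' @examples
#' p <- pk_parameters(0.42, 0.4, 0.00449)
#' bateman_single(p, 600, c(0, 1, 2, 6))
#' @export
bateman_single <- function(params, d, t) {
  .check_params(params)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (d < 0) stop("`d` must be >= 0", call. = FALSE)
  .k_scale(params) * d * (exp(-params$ke * t) - exp(-params$ka * t))
}

#' Dose-history product sums
#'
#' The cycle-n coefficients of the generalized multiple-dose Bateman
#' solution are built from the discounted dose history
#' \code{S(n) = sum_{i<n} d_i prod_{j=i}^{n-1} f_j + d_n} with per-cycle
#' decay factors \code{f_j = alpha_j = exp(-ka*tau_j)} (for the absorbed
#' amount) or \code{beta_j = exp(-ke*tau_j)} (for the eliminated mode).
#' Computed by the forward recursion
#' \code{S(1) = d_1; S(m+1) = f_m S(m) + d_{m+1}}, which reproduces the
#' literal double sum in O(n).
#'
#' @param params \code{\link{pk_parameters}}.
#' @param regimen \code{\link{dose_regimen}}.
#' @param n cycle index in \code{1..n_doses(regimen)}.
#' @return List with \code{n}, \code{S_alpha}, \code{S_beta}.
#' @export
dose_history_sums <- function(params, regimen, n) {
  .check_params(params); .check_regimen(regimen)
  if (length(n) != 1L || n < 1 || n > regimen$n || n != round(n))
    stop("`n` must be a cycle index in 1..", regimen$n, call. = FALSE)
  s <- .history_sums(params, regimen)
  list(n = as.integer(n), S_alpha = s$S_alpha[n], S_beta = s$S_beta[n])
}

# internal: S_alpha(n), S_beta(n) for every cycle at once (forward recursion)
.history_sums <- function(params, regimen) {
  d <- regimen$doses
  alpha <- exp(-params$ka * regimen$intervals)
  beta <- exp(-params$ke * regimen$intervals)
  N <- regimen$n
  Sa <- Sb <- numeric(N)
  Sa[1] <- Sb[1] <- d[1]
  if (N > 1) for (m in 1:(N - 1)) {
    Sa[m + 1] <- alpha[m] * Sa[m] + d[m + 1]
    Sb[m + 1] <- beta[m] * Sb[m] + d[m + 1]
  }
  list(S_alpha = Sa, S_beta = Sb, alpha = alpha, beta = beta)
}

#' Per-cycle exponential-mode coefficients
#'
#' Within cycle \code{n} the concentration is
#' \code{x(t) = C1(n) exp(-ke*(t - t_{n-1})) - C2(n) exp(-ka*(t - t_{n-1}))}.
#' \code{C2(n) = k S_alpha(n)} and \code{C1(n) = k S_beta(n)} with
#' \code{k = ka*gamma/(ka - ke)}; the latter is the algebraic
#' simplification of the three-term form
#' \code{k S_alpha(n) + k (Q_beta(n) - Q_alpha(n))},
#' \code{Q(n) = S(n) - d_n}.
#'
#' @inheritParams dose_history_sums
#' @return List with \code{n}, \code{C1}, \code{C2} and the scale \code{k}.
#' @export
cycle_coefficients <- function(params, regimen, n) {
  s <- dose_history_sums(params, regimen, n)
  k <- .k_scale(params)
  list(n = s$n, C1 = k * s$S_beta, C2 = k * s$S_alpha, k = k)
}

#' Multiple-dose Bateman concentration
#'
#' Evaluates the generalized multiple-dose Bateman function: within cycle
#' \code{n}, \code{x(t) = C1(n) e^{-ke(t-t_{n-1})} - C2(n) e^{-ka(t-t_{n-1})}}
#' with coefficients from \code{\link{cycle_coefficients}}. \code{x} is
#' continuous everywhere, including at dose instants, and \code{x(0) = 0}.
#' For a constant \code{(d, tau)} schedule this reduces to the equi-dose
#' closed form with \code{C1 = k d (1-beta^n)/(1-beta)},
#' \code{C2 = k d (1-alpha^n)/(1-alpha)}.
#'
#' @param params \code{\link{pk_parameters}}.
#' @param regimen \code{\link{dose_regimen}}.
#' @param t numeric vector of times within \code{[0, t_N]}.
#' @return Concentration at each \code{t}.
#' @examples
#' p <- pk_parameters(0.42, 0.4, 0.00449)
#' r <- equidose_regimen(250, 4, 6)
#' concentration(p, r, c(0, 2, 10, 24))
#' @export
concentration <- function(params, regimen, t) {
  .check_params(params); .check_regimen(regimen)
  loc <- cycle_of(regimen, t)
  s <- .history_sums(params, regimen)
  k <- .k_scale(params)
  C1 <- k * s$S_beta[loc$cycle]
  C2 <- k * s$S_alpha[loc$cycle]
  C1 * exp(-params$ke * loc$offset) - C2 * exp(-params$ka * loc$offset)
}

#' Amount awaiting absorption
#'
#' The gastrointestinal (absorption-site) amount
#' \code{y(t) = S_alpha(n) exp(-ka*(t - t_{n-1}))} for \code{t} in cycle
#' \code{n}. Right-continuous at dose instants, where it jumps up by
#' exactly \code{d_n}; \code{y(0) = d_1}.
#'
#' @inheritParams concentration
#' @return Amount at each \code{t}.
#' @export
absorbed_amount <- function(params, regimen, t) {
  .check_params(params); .check_regimen(regimen)
  loc <- cycle_of(regimen, t)
  s <- .history_sums(params, regimen)
  s$S_alpha[loc$cycle] * exp(-params$ka * loc$offset)
}

#' Sampled concentration profile
#'
#' Vectorized evaluation of the closed-form trajectory on a sorted time
#' grid, for export and plotting.
#'
#' @param params \code{\link{pk_parameters}}.
#' @param regimen \code{\link{dose_regimen}} (or \code{\link{fat_regimen}},
#'   which dispatches to the finite-absorption-time solution and adds a
#'   \code{phase} column).
#' @param grid sorted numeric vector of times within \code{[0, t_N]}.
#' @return A data frame of class \code{"concentration_profile"} with
#'   columns \code{t}, \code{x} (concentration), \code{y} (amount awaiting
#'   absorption), \code{cycle}, and for finite-absorption-time regimens
#'   \code{phase} (\code{"assimilation"}/\code{"clearance"}).
#' @export
pk_profile <- function(params, regimen, grid) {
  .check_grid(grid, regimen)
  if (inherits(regimen, "fat_regimen")) return(pbftpk_profile(params, regimen, grid))
  if (length(grid) == 0L) {
    out <- data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      cycle = integer(0))
  } else {
    loc <- cycle_of(regimen, grid)
    out <- data.frame(t = grid,
                      x = concentration(params, regimen, grid),
                      y = absorbed_amount(params, regimen, grid),
                      cycle = loc$cycle)
  }
  class(out) <- c("concentration_profile", "data.frame")
  out
}

.check_grid <- function(grid, regimen) {
  if (!is.numeric(grid)) stop("`grid` must be numeric", call. = FALSE)
  if (length(grid) > 1L && is.unsorted(grid))
    stop("`grid` must be sorted increasing", call. = FALSE)
  invisible(grid)
}
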