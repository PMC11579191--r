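# Multi-dose kinetics with a Finite Absorption Time (F.A.T.): within each
# cycle an assimilation phase [t_{n-1}, s_n] with first-order absorption and
# elimination, then a clearance phase [s_n, t_n] with elimination only
# (the absorption-site amount is depleted at s_n).
#
# Ground truth is the per-cycle recursion derived from the dynamic system
# and its continuity/reset conditions: with residual r_n = x(t_{n-1})
# carried across cycles (r_1 = 0),
#   assimilation: y = d_n e^{-ka (t-t_{n-1})},
#                 x = C1(n) e^{-ke (t-t_{n-1})} - C2(n) e^{-ka (t-t_{n-1})},
#                 C1(n) = k d_n + r_n, C2(n) = k d_n
#   clearance:    y = 0, x = C3(n) e^{-ke (t-s_n)},
#                 C3(n) = C1(n) e^{-ke sigma_n} - C2(n) e^{-ka sigma_n}
#   carryover:    r_{n+1} = C3(n) e^{-ke (tau_n - sigma_n)}
# The published equi-dose closed form is kept as a secondary path (see
# pbftpk_equidose_coefficients); its C3 sum as printed is off by one cycle
# index (it equals the correct C3(n-1) and gives C3(1) = 0, contradicting
# continuity at s_1), so the closed-form path uses the index-corrected sum
# and the discrepancy is documented rather than silently patched.

# internal: recursion coefficients for every cycle of a fat_regimen
.pbftpk_recursion <- function(params, regimen) {
  .check_params(params)
  .check_fat_regimen(regimen)
  k <- .k_scale(params)
  N <- regimen$n
  d <- regimen$doses
  sig <- regimen$fat
  tau <- regimen$intervals
  C1 <- C2 <- C3 <- r <- numeric(N)
  rn <- 0
  for (m in seq_len(N)) {
    r[m] <- rn
    C1[m] <- k * d[m] + rn
    C2[m] <- k * d[m]
    C3[m] <- C1[m] * exp(-params$ke * sig[m]) -
             C2[m] * exp(-params$ka * sig[m])
    rn <- C3[m] * exp(-params$ke * (tau[m] - sig[m]))
  }
  list(C1 = C1, C2 = C2, C3 = C3, r = r, k = k)
}

#' Per-cycle coefficients of the finite-absorption-time solution
#'
#' Recursion-derived mode coefficients for cycle \code{n} of an arbitrary
#' finite-absorption-time regimen: \code{C1}, \code{C2} govern the
#' assimilation phase, \code{C3} the clearance phase, and \code{r} is the
#' residual concentration entering the cycle. They satisfy the carryover
#' identity \code{C1(n) - C2(n) = r_n = (beta/B) C3(n-1)} in the equi-dose
#' case (\code{beta = exp(-ke tau)}, \code{B = exp(-ke sigma)}).
#'
#' @param params \code{\link{pk_parameters}}.
#' @param regimen \code{\link{fat_regimen}}.
#' @param n cycle index.
#' @return List with \code{n}, \code{C1}, \code{C2}, \code{C3}, \code{r}.
#' @export
pbftpk_cycle_coefficients <- function(params, regimen, n) {
  co <- .pbftpk_recursion(params, regimen)
  if (length(n) != 1L || n < 1 || n > regimen$n || n != round(n))
    stop("`n` must be a cycle index in 1..", regimen$n, call. = FALSE)
  list(n = as.integer(n), C1 = co$C1[n], C2 = co$C2[n], C3 = co$C3[n],
       r = co$r[n])
}

#' Published equi-dose closed-form coefficients
#'
#' Evaluates the closed-form coefficients for a constant
#' \code{(d, tau, sigma)} schedule:
#' \code{C2(n) = k d},
#' \code{C1(n) = k d + (beta/B) k (B - A) d (1 - beta^{n-1})/(1 - beta)},
#' \code{C3(n) = k (B - A) d (1 - beta^n)/(1 - beta)}, with
#' \code{A = exp(-ka sigma)}, \code{B = exp(-ke sigma)},
#' \code{beta = exp(-ke tau)}. The \code{C3} sum is index-corrected: the
#' published sum stops one dose short, which would make the first
#' clearance phase identically zero, contradicting continuity at the first
#' absorption cutoff. Agrees with \code{\link{pbftpk_cycle_coefficients}}
#' to machine precision.
#'
#' @param params \code{\link{pk_parameters}}.
#' @param d dose amount.
#' @param tau dosing interval.
#' @param sigma absorption duration, \code{0 < sigma < tau} (use the
#'   recursion path for \code{sigma = tau}).
#' @param n cycle index >= 1.
#' @return List with \code{n}, \code{C1}, \code{C2}, \code{C3}.
#' @export
pbftpk_equidose_coefficients <- function(params, d, tau, sigma, n) {
  .check_equi_inputs(params, d, tau)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0 ||
      sigma >= tau)
    stop("closed form requires 0 < sigma < tau; the recursion path ",
         "(pbftpk_cycle_coefficients) also covers sigma = tau",
         call. = FALSE)
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  k <- .k_scale(params)
  A <- exp(-params$ka * sigma)
  B <- exp(-params$ke * sigma)
  beta <- exp(-params$ke * tau)
  hist_nm1 <- d * (1 - beta^(n - 1)) / (1 - beta)  # sum_{i<n} beta^{n-1-i} d
  list(n = as.integer(n),
       C1 = k * d + (beta / B) * k * (B - A) * hist_nm1,
       C2 = k * d,
       C3 = k * (B - A) * d * (1 - beta^n) / (1 - beta))
}

#' Finite-absorption-time state at given times
#'
#' Evaluates the multi-dose finite-absorption-time solution. During
#' assimilation the absorption-site amount is \code{d_n e^{-ka delta}} and
#' the concentration is the single-dose Bateman term plus the decaying
#' residual; during clearance the amount is zero and the concentration
#' decays mono-exponentially. \code{x} is continuous everywhere (with a
#' derivative kink at each absorption cutoff \code{s_n}); \code{y} resets
#' to \code{d_n} at each dose instant and to 0 at \code{s_n}.
#'
#' @param params \code{\link{pk_parameters}}.
#' @param regimen \code{\link{fat_regimen}}.
#' @param t numeric vector of times within \code{[0, t_N]}.
#' @return List with numeric \code{x}, \code{y} and character
#'   \code{phase} (\code{"assimilation"} or \code{"clearance"}), each the
#'   length of \code{t}.
#' @export
pbftpk_state <- function(params, regimen, t) {
  .check_params(params)
  .check_fat_regimen(regimen)
  loc <- cycle_of(regimen, t)
  co <- .pbftpk_recursion(params, regimen)
  cyc <- loc$cycle
  off <- loc$offset
  sig <- regimen$fat[cyc]
  assim <- off < sig
  x <- y <- numeric(length(t))
  # assimilation phase
  if (any(assim)) {
    i <- which(assim)
    x[i] <- co$C1[cyc[i]] * exp(-params$ke * off[i]) -
            co$C2[cyc[i]] * exp(-params$ka * off[i])
    y[i] <- regimen$doses[cyc[i]] * exp(-params$ka * off[i])
  }
  # clearance phase (includes t == s_n, where y is already depleted)
  if (any(!assim)) {
    i <- which(!assim)
    x[i] <- co$C3[cyc[i]] * exp(-params$ke * (off[i] - sig[i]))
    y[i] <- 0
  }
  list(x = x, y = y,
       phase = ifelse(assim, "assimilation", "clearance"))
}

#' Sampled finite-absorption-time profile
#'
#' @inheritParams pbftpk_state
#' @param grid sorted numeric vector of times within \code{[0, t_N]}.
#' @return A \code{"concentration_profile"} data frame with columns
#'   \code{t}, \code{x}, \code{y}, \code{cycle}, \code{phase}.
#' @export
pbftpk_profile <- function(params, regimen, grid) {
  .check_fat_regimen(regimen)
  .check_grid(grid, regimen)
  if (length(grid) == 0L) {
    out <- data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      cycle = integer(0), phase = character(0))
  } else {
    st <- pbftpk_state(params, regimen, grid)
    out <- data.frame(t = grid, x = st$x, y = st$y,
                      cycle = cycle_of(regimen, grid)$cycle,
                      phase = st$phase)
  }
  class(out) <- c("concentration_profile", "data.frame")
  out
}
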