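#' Multi-dose intravenous bolus concentration
#'
#' One-compartment elimination-only kinetics under repeated bolus
#' injections. Doses are concentration increments \code{delta_n}
#' (mass/volume, e.g. mg/mL) — unlike the oral models, no volume division
#' is applied. Within cycle \code{n},
#' \code{x(t) = S_beta(n) exp(-ke (t - t_{n-1}))} where
#' \code{S_beta(n) = sum_{i<n} delta_i prod_{j=i}^{n-1} beta_j + delta_n},
#' \code{beta_j = exp(-ke tau_j)}. \code{x} is right-continuous at dose
#' instants, jumping up by exactly \code{delta_n}, and decays
#' mono-exponentially in between; by linearity this equals the plain
#' superposition \code{sum_{i<=n} delta_i exp(-ke (t - t_{i-1}))}.
#'
#' @param ke elimination rate constant, > 0 (1/time).
#' @param regimen \code{\link{dose_regimen}} whose doses are concentration
#'   increments.
#' @param t numeric vector of times within \code{[0, t_N]}.
#' @return Concentration at each \code{t}.
#' @examples
#' r <- equidose_regimen(600, 6, 6)
#' bolus_concentration(0.3838, r, c(0, 3, 15))
#' @export
bolus_concentration <- function(ke, regimen, t) {
  .check_ke(ke)
  .check_regimen(regimen)
  loc <- cycle_of(regimen, t)
  Sb <- .bolus_sums(ke, regimen)
  Sb[loc$cycle] * exp(-ke * loc$offset)
}

# internal: forward recursion for the beta-discounted dose history
.bolus_sums <- function(ke, regimen) {
  beta <- exp(-ke * regimen$intervals)
  d <- regimen$doses
  N <- regimen$n
  Sb <- numeric(N)
  Sb[1] <- d[1]
  if (N > 1) for (m in 1:(N - 1)) Sb[m + 1] <- beta[m] * Sb[m] + d[m + 1]
  Sb
}

#' Sampled bolus concentration profile
#'
#' @inheritParams bolus_concentration
#' @param grid sorted numeric vector of times within \code{[0, t_N]}.
#' @return A \code{"concentration_profile"} data frame with columns
#'   \code{t}, \code{x}, \code{cycle} (no absorption state for bolus
#'   dosing).
#' @export
bolus_profile <- function(ke, regimen, grid) {
  .check_ke(ke)
  .check_regimen(regimen)
  .check_grid(grid, regimen)
  if (length(grid) == 0L) {
    out <- data.frame(t = numeric(0), x = numeric(0), cycle = integer(0))
  } else {
    loc <- cycle_of(regimen, grid)
    out <- data.frame(t = grid, x = bolus_concentration(ke, regimen, grid),
                      cycle = loc$cycle)
  }
  class(out) <- c("concentration_profile", "data.frame")
  out
}

.check_ke <- function(ke) {
  if (!is.numeric(ke) || length(ke) != 1L || !is.finite(ke) || ke <= 0)
    stop("`ke` must be a single finite positive number", call. = FALSE)
  invisible(ke)
}
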