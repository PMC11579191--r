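#' One-compartment pharmacokinetic parameters
#'
#' Bundles the absorption rate constant \code{ka}, the elimination rate
#' constant \code{ke} (both 1/time) and the lumped constant \code{gamma}
#' (1/volume) that maps absorbed amount to plasma concentration, so that the
#' single-dose curve is \code{ka*gamma*d/(ka-ke) * (exp(-ke*t) - exp(-ka*t))}.
#' For oral dosing \code{gamma = F/V} (absolute bioavailability over volume
#' of distribution); either supply \code{gamma} directly or both \code{F}
#' and \code{V}.
#'
#' The flip-flop ordering \code{ka < ke} (absorption slower than
#' elimination) is permitted. Exact equality \code{ka == ke} is rejected:
#' all closed forms divide by \code{ka - ke}, and the confluent case is
#' rarely met in practice; no \code{t*exp(-k*t)} limit branch is provided.
#'
#' @param ka absorption rate constant, > 0 (1/time).
#' @param ke elimination rate constant, > 0 (1/time).
#' @param gamma lumped bioavailability/volume constant (1/volume). If
#'   missing, computed as \code{F/V}.
#' @param F absolute bioavailability (dimensionless), optional provenance.
#' @param V volume of distribution, optional provenance.
#' @param rel_tol minimum relative separation of \code{ka} and \code{ke};
#'   draws closer than this are rejected as numerically confluent.
#' @return An object of class \code{"pk_parameters"}.
#' @examples
#' pk_parameters(ka = 0.42, ke = 0.40, gamma = 0.00449)
#' pk_parameters(ka = 1.2, ke = 0.3, F = 0.9, V = 200)
#' @export
pk_parameters <- function(ka, ke, gamma = NULL, F = NULL, V = NULL,
                          rel_tol = 1e-9) {
  if (!is.numeric(ka) || length(ka) != 1L || !is.finite(ka) || ka <= 0)
    stop("`ka` must be a single finite positive number", call. = FALSE)
  if (!is.numeric(ke) || length(ke) != 1L || !is.finite(ke) || ke <= 0)
    stop("`ke` must be a single finite positive number", call. = FALSE)
  if (abs(ka - ke) / max(ka, ke) <= rel_tol)
    stop("`ka` and `ke` must differ (relative separation <= ", rel_tol,
         "): the model's closed forms divide by ka - ke and the ",
         "confluent case ka == ke is out of scope", call. = FALSE)
  if (is.null(gamma)) {
    if (is.null(F) || is.null(V))
      stop("supply `gamma`, or both `F` and `V` so that gamma = F/V",
           call. = FALSE)
    gamma <- F / V
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("`gamma` must be a single finite positive number", call. = FALSE)
  structure(
    list(ka = as.numeric(ka), ke = as.numeric(ke),
         gamma = as.numeric(gamma),
         F = if (is.null(F)) NA_real_ else as.numeric(F),
         V = if (is.null(V)) NA_real_ else as.numeric(V)),
    class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("One-compartment PK parameters\n")
  cat(sprintf("  ka    = %g (1/time)\n", x$ka))
  cat(sprintf("  ke    = %g (1/time)%s\n", x$ke,
              if (x$ka < x$ke) "  [flip-flop kinetics]" else ""))
  cat(sprintf("  gamma = %g (1/volume)\n", x$gamma))
  if (!is.na(x$F)) cat(sprintf("  F = %g, V = %g\n", x$F, x$V))
  invisible(x)
}

# internal: the shared concentration scale ka*gamma/(ka-ke)
.k_scale <- function(params) {
  params$ka * params$gamma / (params$ka - params$ke)
}

.check_params <- function(params) {
  if (!inherits(params, "pk_parameters"))
    stop("`params` must be a pk_parameters object", call. = FALSE)
  invisible(params)
}
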