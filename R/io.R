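# Configuration parsing and profile export for the command-line surface.
# A simulation config is a JSON document:
# {
#   "model": "oral" | "bolus" | "pbftpk",
#   "parameters": {"ka": ..., "ke": ..., "gamma": ...},
#   "regimen": {"type": "equi", "d": ..., "tau": ..., "n_doses": ...}
#            | {"type": "custom", "doses": [...], "intervals": [...]},
#   (pbftpk only) "regimen": {..., "fat": scalar | [...]},
#   "grid": {"step": ...} | {"times": [...]},
#   "units": {"time": "h", "amount": "mg", "volume": "mL"}   (optional)
# }

#' Parse and validate a simulation configuration
#'
#' Validates the whole document and reports every schema violation at
#' once, not just the first.
#'
#' @param text a JSON string (or a list already decoded from JSON).
#' @return A validated config: list with \code{model}, \code{params}
#'   (\code{\link{pk_parameters}}, or bare \code{ke} for bolus),
#'   \code{regimen} (\code{\link{dose_regimen}}/\code{\link{fat_regimen}}),
#'   \code{grid} (numeric times or \code{NULL}), \code{units}.
#' @export
parse_config <- function(text) {
  cfg <- if (is.character(text)) jsonlite::fromJSON(text) else text
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  model <- cfg$model
  if (is.null(model) || !model %in% c("oral", "bolus", "pbftpk")) {
    note("model: must be one of \"oral\", \"bolus\", \"pbftpk\"")
    model <- "oral"
  }
  p <- cfg$parameters
  if (is.null(p)) note("parameters: missing block")
  need <- if (model == "bolus") "ke" else c("ka", "ke", "gamma")
  for (f in need)
    if (is.null(p[[f]]) || !is.numeric(p[[f]]) || p[[f]] <= 0)
      note(paste0("parameters.", f, ": required positive number"))

  r <- cfg$regimen
  if (is.null(r)) {
    note("regimen: missing block")
  } else if (identical(r$type, "equi")) {
    if (is.null(r$d) || !is.numeric(r$d) || r$d < 0)
      note("regimen.d: required nonnegative number")
    if (is.null(r$tau) || !is.numeric(r$tau) || r$tau <= 0)
      note("regimen.tau: required positive number")
    if (is.null(r$n_doses) || !is.numeric(r$n_doses) || r$n_doses < 1)
      note("regimen.n_doses: required count >= 1")
  } else if (identical(r$type, "custom")) {
    if (is.null(r$doses) || !is.numeric(r$doses) || any(r$doses < 0))
      note("regimen.doses: required nonnegative numeric array")
    if (is.null(r$intervals) || !is.numeric(r$intervals) ||
        any(r$intervals <= 0))
      note("regimen.intervals: required positive numeric array")
    if (!is.null(r$doses) && !is.null(r$intervals) &&
        length(r$doses) != length(r$intervals))
      note("regimen.doses/intervals: lengths differ")
  } else {
    note("regimen.type: must be \"equi\" or \"custom\"")
  }
  if (!is.null(r$fat) && model != "pbftpk")
    note("regimen.fat: only valid with model \"pbftpk\"")
  if (model == "pbftpk" && is.null(r$fat))
    note("regimen.fat: required for model \"pbftpk\"")

  grid <- NULL
  if (!is.null(cfg$grid)) {
    if (!is.null(cfg$grid$times)) {
      if (!is.numeric(cfg$grid$times) || is.unsorted(cfg$grid$times))
        note("grid.times: must be a sorted numeric array")
      else grid <- as.numeric(cfg$grid$times)
    } else if (!is.null(cfg$grid$step)) {
      if (!is.numeric(cfg$grid$step) || cfg$grid$step <= 0)
        note("grid.step: must be > 0")
      else grid <- cfg$grid$step
    } else note("grid: needs \"step\" or \"times\"")
  }

  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)

  params <- if (model == "bolus") as.numeric(p$ke)
            else pk_parameters(p$ka, p$ke, p$gamma)
  regimen <- if (identical(r$type, "equi"))
    equidose_regimen(r$d, r$tau, r$n_doses)
  else dose_regimen(r$doses, r$intervals)
  if (model == "pbftpk") regimen <- fat_regimen(regimen, r$fat)
  if (is.numeric(grid) && length(grid) == 1L && !is.null(cfg$grid$step)) {
    tN <- regimen$times[regimen$n + 1L]
    grid <- seq(0, tN, by = grid)
    if (grid[length(grid)] < tN) grid <- c(grid, tN)
  }
  list(model = model, params = params, regimen = regimen, grid = grid,
       units = cfg$units)
}

#' Read and validate a configuration file
#' @param path path to a JSON config file.
#' @return See \code{\link{parse_config}}.
#' @export
read_config <- function(path) {
  parse_config(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Run the simulation described by a parsed config
#'
#' @param config result of \code{\link{parse_config}}.
#' @return A \code{"concentration_profile"} data frame.
#' @export
simulate_config <- function(config) {
  grid <- config$grid
  if (is.null(grid)) {
    tN <- config$regimen$times[config$regimen$n + 1L]
    grid <- seq(0, tN, length.out = 201L)
  }
  switch(config$model,
         oral = pk_profile(config$params, config$regimen, grid),
         bolus = bolus_profile(config$params, config$regimen, grid),
         pbftpk = pbftpk_profile(config$params, config$regimen, grid))
}

#' Write a concentration profile to CSV
#'
#' Full double precision (17 significant digits), deterministic byte
#' output for a fixed profile; columns are \code{t,x[,y][,cycle][,phase]}
#' as present in the profile.
#'
#' @param profile a \code{"concentration_profile"} data frame.
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  if (!is.data.frame(profile))
    stop("`profile` must be a concentration profile data frame",
         call. = FALSE)
  out <- profile
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reproducible corpus of random parameter/regimen pairs
#'
#' Draws property-test fixtures: rate constants log-uniform in
#' \code{[0.05, 2]} per hour (redrawn when closer than 1\% relative, the
#' validity margin), \code{gamma} log-uniform in \code{[1e-4, 1e-2]},
#' 1-20 doses with intervals uniform in \code{[1, 24]} h and doses
#' uniform in \code{[0, 1000]}. Flip-flop orderings arise naturally
#' (about half the draws). The global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param n_cases number of pairs to draw.
#' @param fat if \code{TRUE}, attach absorption cutoffs uniform in
#'   \code{(0, tau_n]} and cap the schedule at 10 doses.
#' @return List of \code{list(params =, regimen =)} pairs.
#' @export
fixture_regimens <- function(seed, n_cases, fat = FALSE) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    repeat {
      ka <- exp(runif(1, log(0.05), log(2)))
      ke <- exp(runif(1, log(0.05), log(2)))
      if (abs(ka - ke) / max(ka, ke) > 0.01) break
    }
    gamma <- exp(runif(1, log(1e-4), log(1e-2)))
    N <- sample(if (fat) 10L else 20L, 1)
    tau <- runif(N, 1, 24)
    d <- runif(N, 0, 1000)
    reg <- dose_regimen(d, tau)
    if (fat) reg <- fat_regimen(reg, tau * runif(N, 1e-6, 1))
    list(params = pk_parameters(ka, ke, gamma), regimen = reg)
  })
}
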