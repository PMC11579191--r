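test_that("per-cycle AUC matches adaptive quadrature and its limits", {
  d <- 600; tau <- 5
  r <- equidose_regimen(d, tau, 6)
  for (n in c(1, 3, 6)) {
    quad <- auc_numeric(function(t) concentration(p_oral, r, t),
                        (n - 1) * tau, n * tau, tol = 1e-12)
    expect_equal(auc_cycle(p_oral, d, tau, n), quad, tolerance = 1e-8)
  }
  # n -> infinity: per-cycle AUC approaches the single-dose total
  expect_equal(auc_cycle(p_oral, d, tau, 1e6),
               auc_single_infinite(p_oral, d), tolerance = 1e-10)
  expect_equal(auc_cycle(p_oral, 0, tau, 3), 0)
})

test_that("single-dose total AUC equals gamma*d/ke and its quadrature", {
  d <- 600
  expect_equal(auc_single_infinite(p_oral, d), p_oral$gamma * d / p_oral$ke,
               tolerance = 1e-14)
  Tend <- 50 / p_oral$ke
  quad <- auc_numeric(function(t) bateman_single(p_oral, d, t), 0, Tend,
                      tol = 1e-10)
  expect_equal(auc_single_infinite(p_oral, d), quad, tolerance = 1e-6)
  expect_equal(auc_single_infinite(p_oral, 0), 0)
})

test_that("peak time matches a numerical argmax and decreases across cycles", {
  d <- 600; tau <- 5
  # first cycle: classic single-dose peak time
  expect_equal(t_max_cycle(p_oral, d, tau, 1),
               log(p_oral$ka / p_oral$ke) / (p_oral$ka - p_oral$ke),
               tolerance = 1e-12)
  r <- equidose_regimen(d, tau, 60)
  num <- optimize(function(t) concentration(p_oral, r, t),
                  c(4 * tau, 5 * tau), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(t_max_cycle(p_oral, d, tau, 5), num, tolerance = 1e-6)
  offs <- vapply(1:50, function(n)
    t_max_cycle(p_oral, d, tau, n) - (n - 1) * tau, numeric(1))
  # strictly decreasing until convergence saturates machine precision
  expect_true(all(diff(offs) < 1e-12))
  expect_true(all(diff(offs[1:10]) < 0))
  expect_true(all(offs > 0))
})

test_that("peak concentration power form equals direct evaluation", {
  d <- 600; tau <- 5
  for (n in c(1, 2, 7, 30)) {
    tm <- t_max_cycle(p_oral, d, tau, n)
    r <- equidose_regimen(d, tau, max(n, 2))
    expect_equal(x_max_cycle(p_oral, d, tau, n),
                 concentration(p_oral, r, tm), tolerance = 1e-12)
  }
  # single-dose Cmax closed form
  k <- p_oral$ka * p_oral$gamma / (p_oral$ka - p_oral$ke)
  rho <- p_oral$ka / p_oral$ke; ex <- 1 / (p_oral$ka - p_oral$ke)
  cmax1 <- k * d * (rho^(-p_oral$ke * ex) - rho^(-p_oral$ka * ex))
  expect_equal(x_max_cycle(p_oral, d, tau, 1), cmax1, tolerance = 1e-13)
  # peaks increase toward the steady-state ceiling
  xm <- vapply(1:200, function(n) x_max_cycle(p_oral, d, tau, n), numeric(1))
  expect_true(all(diff(xm) >= 0))
  expect_true(all(diff(xm[1:10]) > 0))
  expect_equal(xm[200],
               unname(steady_state_bounds(p_oral, d, tau)["ss_upper"]),
               tolerance = 1e-6)
})

test_that("clipped interior peaks fall back to the true in-cycle argmax", {
  # tau shorter than the single-dose peak time (~2.44 h here)
  expect_warning(tm <- t_max_cycle(p_oral, 600, 2, 1), "clipped|boundary")
  r <- equidose_regimen(600, 2, 2)
  num <- optimize(function(t) concentration(p_oral, r, t), c(0, 2),
                  maximum = TRUE, tol = 1e-10)
  expect_equal(tm, num$maximum, tolerance = 1e-6)
  expect_equal(x_max_cycle(p_oral, 600, 2, 1),
               concentration(p_oral, r, tm), tolerance = 1e-12)
})

test_that("the trough remainder equals the cycle-end concentration", {
  d <- 600; tau <- 5
  r <- equidose_regimen(d, tau, 10)
  for (n in c(1, 4, 9))
    expect_equal(remainder(p_oral, d, tau, n),
                 concentration(p_oral, r, n * tau), tolerance = 1e-12)
  # positivity, including flip-flop kinetics, and monotone accumulation
  pf <- pk_parameters(0.2, 0.8, 0.001)
  rem <- remainder(pf, 100, 6, 1:100)
  expect_true(all(rem > 0))
  expect_true(all(diff(rem) >= 0))
  expect_true(all(diff(rem[1:10]) > 0))
  expect_true(all(diff(remainder(p_oral, d, tau, 1:100)) >= 0))
  expect_true(all(diff(remainder(p_oral, d, tau, 1:10)) > 0))
  # n -> infinity: trough limit is the lower steady-state bound
  expect_equal(remainder(p_oral, d, tau, 1e6),
               unname(steady_state_bounds(p_oral, d, tau)["ss_lower"]),
               tolerance = 1e-12)
})

test_that("steady-state bounds bracket a long simulated trajectory", {
  d <- 600; tau <- 5
  b <- steady_state_bounds(p_oral, d, tau)
  r <- equidose_regimen(d, tau, 300)
  tt <- seq(299 * tau, 300 * tau, length.out = 20001)
  x <- concentration(p_oral, r, tt)
  expect_equal(min(x), unname(b["ss_lower"]), tolerance = 1e-6)
  expect_equal(max(x), unname(b["ss_upper"]), tolerance = 1e-6)
  expect_gt(b["ss_lower"], 0)
  expect_gt(b["ss_upper"], b["ss_lower"])
  # linearity in dose
  b2 <- steady_state_bounds(p_oral, 2 * d, tau)
  expect_equal(unname(b2), 2 * unname(b), tolerance = 1e-14)
})

test_that("bounds are monotone in dose and interval with the right limits", {
  ds <- seq(100, 1000, length.out = 20)
  taus <- seq(2, 48, length.out = 20)
  for (tau in c(2, 12, 48)) {
    lo <- vapply(ds, function(d)
      unname(steady_state_bounds(p_oral, d, tau)["ss_lower"]), numeric(1))
    hi <- vapply(ds, function(d)
      unname(steady_state_bounds(p_oral, d, tau)["ss_upper"]), numeric(1))
    expect_true(all(diff(lo) > 0) && all(diff(hi) > 0))
  }
  for (d in c(100, 550, 1000)) {
    lo <- vapply(taus, function(tau)
      unname(steady_state_bounds(p_oral, d, tau)["ss_lower"]), numeric(1))
    hi <- vapply(taus, function(tau)
      unname(steady_state_bounds(p_oral, d, tau)["ss_upper"]), numeric(1))
    expect_true(all(diff(lo) < 0) && all(diff(hi) < 0))
  }
  # tau -> infinity: troughs vanish, peaks approach the single-dose Cmax
  tau_big <- 1e3 / min(p_oral$ka, p_oral$ke)
  b <- steady_state_bounds(p_oral, 600, tau_big)
  expect_lt(b["ss_lower"], 1e-10)
  expect_equal(unname(b["ss_upper"]), x_max_cycle(p_oral, 600, tau_big, 1),
               tolerance = 1e-10)
})

test_that("therapeutic width is positive, linear in d, with the long-interval limit", {
  for (d in seq(100, 1000, length.out = 20))
    for (tau in seq(2, 48, length.out = 20))
      expect_gt(therapeutic_width(p_oral, d, tau), 0)
  expect_equal(therapeutic_width(p_oral, 1200, 6),
               2 * therapeutic_width(p_oral, 600, 6), tolerance = 1e-13)
  k <- p_oral$ka * p_oral$gamma / (p_oral$ka - p_oral$ke)
  rho <- p_oral$ka / p_oral$ke; ex <- 1 / (p_oral$ka - p_oral$ke)
  lim <- k * 600 * (rho^(-p_oral$ke * ex) - rho^(-p_oral$ka * ex))
  expect_equal(therapeutic_width(p_oral, 600, 1e3), lim, tolerance = 1e-6)
})

test_that("periodicity gaps match a dense grid sup and decay geometrically", {
  d <- 600; tau <- 5
  alpha <- exp(-p_oral$ka * tau); beta <- exp(-p_oral$ke * tau)
  k <- p_oral$ka * p_oral$gamma / (p_oral$ka - p_oral$ke)
  grid_sup <- function(n) {
    s <- seq(0, tau, length.out = 1e5)
    dC1 <- k * d * beta^(n - 1); dC2 <- k * d * alpha^(n - 1)
    max(abs(dC1 * exp(-p_oral$ke * s) - dC2 * exp(-p_oral$ka * s)))
  }
  for (n in c(2, 5, 20))
    expect_equal(periodicity_gap(p_oral, d, tau, n), grid_sup(n),
                 tolerance = 1e-8)
  g <- periodicity_gap(p_oral, d, tau, 2:60)
  expect_true(all(g[-1] < g[-length(g)] | g[-1] == 0))
  ratio <- g[50] / g[49]
  expect_equal(ratio, max(alpha, beta), tolerance = 0.01)
  expect_equal(periodicity_gap(p_oral, 0, tau, 2:10), rep(0, 9))
  expect_error(periodicity_gap(p_oral, d, tau, 1), ">= 2")
})

test_that("the epsilon-steady-state index is certified and monotone in eps", {
  d <- 600; tau <- 5
  n1 <- n_epsilon(p_oral, d, tau, 1e-6)
  gaps <- periodicity_gap(p_oral, d, tau, 2:(n1 + 100))
  expect_true(all(gaps[(n1 - 1):length(gaps)] < 1e-6))
  expect_gte(gaps[n1 - 2], 1e-6) # n1 is the first qualifying cycle
  expect_lte(n_epsilon(p_oral, d, tau, periodicity_gap(p_oral, d, tau, 2) * 2), 2)
  eps_seq <- 10^seq(-2, -10, by = -1)
  ns <- vapply(eps_seq, function(e) n_epsilon(p_oral, d, tau, e), integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("the steady-state summary bundles consistent asymptotics", {
  s <- steady_state_summary(p_oral, 600, 5, eps = 1e-6)
  expect_equal(s$auc_ss, auc_single_infinite(p_oral, 600), tolerance = 1e-12)
  expect_equal(s$width, s$ss_upper - s$ss_lower, tolerance = 1e-14)
  # envelope brackets the trajectory well past the certified index
  n_far <- s$n_eps + 50
  r <- equidose_regimen(600, 5, n_far)
  tt <- seq((n_far - 1) * 5, n_far * 5, length.out = 5001)
  x <- concentration(p_oral, r, tt)
  expect_true(all(x >= s$ss_lower - s$eps & x <= s$ss_upper + s$eps))
  expect_error(steady_state_summary(p_oral, 0, 5), "degenerate")
})

test_that("the steady-state AUC identity is exact for random parameters", {
  set.seed(3)
  for (i in 1:25) {
    case <- fixture_regimens(300 + i, 1)[[1]]
    p <- case$params
    d <- runif(1, 50, 1000); tau <- runif(1, 1, 24)
    auc_ss <- steady_state_summary(p, d, tau, eps = 1e-3)$auc_ss
    expect_equal(auc_ss, auc_single_infinite(p, d), tolerance = 1e-12)
  }
})
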