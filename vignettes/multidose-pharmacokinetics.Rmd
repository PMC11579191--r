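---
title: "Multi-dose pharmacokinetics: models, closed forms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-dose pharmacokinetics: models, closed forms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multidosepk)
```

## The model

`multidosepk` works with the one-compartment disposition model with
first-order absorption and elimination. After a single oral dose $d$ the
gut amount $y$ and the plasma concentration $x$ obey

$$y' = -\kappa_a y, \qquad x' = \kappa_a \gamma\, y - \kappa_e x,
\qquad y(0) = d,\; x(0) = 0,$$

whose solution for $x$ is the Bateman function
$k\,d\,(e^{-\kappa_e t} - e^{-\kappa_a t})$ with
$k = \kappa_a\gamma/(\kappa_a - \kappa_e)$. Repeated dosing adds discrete
events to this continuous flow: at each dose time $t_{n-1}$ the gut
amount jumps up by the dose $d_n$ while $x$ stays continuous (oral
intake does not raise systemic concentration instantaneously). The
package evaluates the exact solution of this impulsive system under any
finite schedule $\{(\tau_n, d_n)\}$: within cycle
$I_n = [t_{n-1}, t_n)$,

$$x(t) = C_1(n)\, e^{-\kappa_e (t - t_{n-1})} -
         C_2(n)\, e^{-\kappa_a (t - t_{n-1})},$$

where the coefficients absorb the entire dose history through the
discounted sums
$S_f(n) = \sum_{i<n} d_i \prod_{j=i}^{n-1} f_j + d_n$ with per-cycle
decay factors $f_j = \alpha_j = e^{-\kappa_a \tau_j}$ or
$\beta_j = e^{-\kappa_e \tau_j}$. Two companion models share the cycle
bookkeeping: intravenous bolus dosing (elimination only, $x$ itself
jumps by the administered concentration increment) and
finite-absorption-time kinetics (below).

### Assumptions

* Linear kinetics: doses superpose, all quantities scale linearly in
  dose. This is what makes the dose-history sums and the regimen-design
  decomposition exact.
* $\kappa_a \ne \kappa_e$. The confluent case has a different functional
  form ($t\,e^{-\kappa t}$) and is rare in practice; the constructors
  reject rate constants within relative `rel_tol` ($10^{-9}$ by default)
  of each other rather than switching branches silently. The flip-flop
  ordering $\kappa_a < \kappa_e$ is fully supported.
* Schedules are finite. The theory's schedules are conceptually
  infinite, but only one cycle is ever active at a time; we truncate at
  $N$ doses and treat evaluation beyond $t_N$ as a domain error instead
  of extrapolating. A washout tail is modelled by appending a zero dose
  with a long interval — a zero dose and a lengthened interval produce
  identical trajectories (tested).

## Parameters and units

| parameter | meaning | unit | worked default |
|---|---|---|---|
| `ka` | absorption rate constant | 1/h | 0.42 |
| `ke` | elimination rate constant | 1/h | 0.40 |
| `gamma` | $F/V$, amount-to-concentration scale | 1/mL | 0.00449 |
| `d`, `tau` | dose and interval | mg, h | 600 mg / 5 h |
| `sigma` | finite absorption time per cycle | h | 2 |

Units are documented, never enforced: the library is unit-agnostic and
any consistent system works. `gamma` is supplied directly or as `F/V`;
for bolus dosing the doses are already concentrations and no volume
division is applied — the single deliberate asymmetry between routes.

## Numerical choices

**Forward recursion, not the literal double sum.** $S_f(n)$ is computed
by $S(1) = d_1$, $S(m+1) = f_m S(m) + d_{m+1}$ — O(N) instead of
O(N²) and algebraically identical; the literal double sum is kept in the
test suite as an independent reference. The eliminated-mode coefficient
is computed as $C_1(n) = k\,S_\beta(n)$, the algebraic simplification of
the three-term form $k S_\alpha + k(Q_\beta - Q_\alpha)$; both forms are
cross-checked to machine precision in the tests, which doubles as a
verification of the underlying algebra.

**Boundary conventions.** Cycles are half-open: a dose instant belongs to
the cycle it opens, so $y$ is right-continuous with jump $d_n$ and $x$ is
continuous from both sides. Lookup is a binary search
(`findInterval`) checked against a linear scan property test. The
schedule end $t_N$ maps to the last cycle.

**Geometric factors.** Terms like $(1-\alpha^n)/(1-\alpha)$ are evaluated
directly: $\alpha = e^{-\kappa_a \tau} < 1$ strictly because
$\kappa_a, \tau > 0$, so no special casing is needed.

**Clipped peaks.** The interior critical point of a cycle,
$\ln(\kappa_a C_2/\kappa_e C_1)/(\kappa_a-\kappa_e)$ past the cycle
start, can fall beyond $\tau$ when the interval is shorter than the
single-dose peak time. `t_max_cycle()` then returns the boundary argmax
and warns; `x_max_cycle()` follows the same rule, so the pair always
reports the true in-cycle maximum rather than a formula value outside
the cycle.

**Certifying the steady-state index.** The epsilon-steady-state index
demands that *all* later successive-cycle gaps stay below the tolerance.
Scanning infinitely many cycles is impossible; instead we use the
envelope $\mathrm{gap}(m) \le k d (\beta^{m-1} + \alpha^{m-1})$, which
decays geometrically. Gaps are checked explicitly until the envelope
itself drops under the tolerance, at which point no later gap can
resurface, and the first cycle of the verified run is returned. This
avoids assuming the gaps are monotone from the start (only their
eventual decay is guaranteed).

**Regimen design.** The existence of an effective schedule for any
prescribed window is a theoretical result without an algorithm attached.
The package's algorithmic contribution is the observation that both
envelope bounds are linear in $d$, so their ratio depends on $\tau$
alone, is $>1$, tends to $1^+$ as $\tau \to 0$ and grows without bound —
a monotone scalar problem. We root-find the ratio on a geometrically
expanded bracket within $[10^{-6}, 10^{6}]$ time units (monotonicity is
re-checked on the bracket and violations abort loudly), then scale the
dose. Root tolerance is machine epsilon; the round trip from a known
schedule recovers $\tau$ to $10^{-6}$ and $d$ to $10^{-8}$ relative. The
effectiveness predicate allows $10^{-9}$ relative slack at the window
edges so designs that sit exactly on the boundary are not rejected for
one ulp.

## Finite absorption time

The finite-absorption-time model splits each cycle at the cutoff
$s_n = t_{n-1} + \sigma_n$: absorption and elimination act on
$[t_{n-1}, s_n]$, then the gut amount is depleted and only elimination
acts on $[s_n, t_n]$. The package's ground truth is the per-cycle
recursion that follows directly from the dynamic system and its
continuity/reset conditions: with residual $r_n = x(t_{n-1})$,

$$C_1(n) = k d_n + r_n,\quad C_2(n) = k d_n,\quad
C_3(n) = C_1(n) B_n - C_2(n) A_n,\quad
r_{n+1} = C_3(n)\, e^{-\kappa_e(\tau_n - \sigma_n)},$$

with $A_n = e^{-\kappa_a \sigma_n}$, $B_n = e^{-\kappa_e \sigma_n}$. This
covers fully irregular schedules and $\sigma_n = \tau_n$ (degenerate
clearance phase). The published equi-dose closed form is implemented as
a secondary path and cross-checked: its clearance coefficient, as
printed, sums the dose history one dose short — taken literally it makes
the first clearance phase identically zero, contradicting continuity at
the first cutoff, while the same sum appears (correctly) as the
carried-over residual inside $C_1(n)$. Our closed-form path therefore
uses the index-corrected sum, the recursion-vs-closed-form agreement is
asserted to $10^{-12}$ for 20 cycles, and the carryover identity
$C_1(n) - C_2(n) = (\beta/B)\,C_3(n-1)$ is tested rather than assumed.
With $\sigma_n = \tau_n$ the within-cycle concentration update matches
the oral model given the same entering state, but full trajectories
differ by design: the oral model carries leftover gut amount across
cycles, the finite-absorption model resets it.

## The verification oracle

Every closed form is checked against `integrate_multidose()`, which
integrates the raw impulsive ODE systems with `deSolve::lsoda`
(tolerances $10^{-12}$ by default), restarting at every event with the
jump applied to the state. The oracle deliberately uses no analytical
solution and no per-segment matrix exponential — adaptive numerical
integration only — so agreement (maximum relative deviation $<10^{-6}$
across the worked parameter sets and 100 random regimens per model) is
evidence, not circularity. AUC formulas are checked against
`stats::integrate` adaptive quadrature with a pure relative target.

## Random fixtures: what they cover and what they do not

`fixture_regimens()` draws rate constants log-uniform in
$[0.05, 2]\,\mathrm{h}^{-1}$ (rejecting pairs within 1% relative — the
near-confluent regime is excluded by the model contract), $\gamma$
log-uniform in $[10^{-4}, 10^{-2}]\,\mathrm{mL}^{-1}$, up to 20 doses
with intervals of 1–24 h and doses of 0–1000 mg. These ranges bracket
typical small-molecule oral kinetics and include flip-flop orderings in
roughly half the draws. They do **not** emulate real data: there is no
measurement noise, no between-subject variability, no nonlinear
(saturable) elimination, no lag time, and no parameter uncertainty.
Passing tests therefore demonstrate the mathematical correctness of the
solutions and metrics under the model, not predictive accuracy for any
particular drug.

Problem sizes used throughout the suite — 100 random regimens per model
for oracle comparison, 300 cycles for steady-state simulation, 20 000
grid points for extremum location, 50 random design targets — were
chosen so each check is decisive at its stated tolerance while the whole
suite stays interactive.

## Known limitations

* One compartment only; no transit-compartment chains, no covariates, no
  infusion models.
* Equi-dose metrics (AUC per cycle, peaks, troughs, envelope) are
  closed-form for constant $(d, \tau)$ only, mirroring the scope of the
  underlying asymptotic theory; irregular-schedule metrics are available
  numerically via the quadrature oracle.
* No parameter estimation: $(\kappa_a, \kappa_e, \gamma)$ are inputs.
  Regimen design is exact for the model but only as good as those
  parameters — in practice they are uncertain, which is why the design
  functions are decision-support, not prescriptions.
* The "therapeutic range" computed here is the model's asymptotic
  concentration envelope; it coincides with a clinical efficacy/safety
  window only when the prescriber makes it so via `design_regimen()`.
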