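Package: multidosepk
Title: Closed-Form Multi-Dose Pharmacokinetics Under Arbitrary Dosing Regimens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical blood-concentration dynamics for repeated drug
    administration under a one-compartment model with first-order
    absorption and elimination. Implements the multiple-dose Bateman
    function for equi-dose and fully irregular oral regimens, multi-dose
    intravenous bolus decay, and multi-dose kinetics with a finite
    absorption time (assimilation/clearance phases), together with
    per-cycle pharmacokinetic metrics (AUC, peak time and value, trough
    remainder), steady-state accumulation bounds and therapeutic-range
    width, and regimen design that inverts the steady-state envelope to a
    dose and dosing interval. Every closed form is verified against an
    independent numerical integrator for the underlying impulsive ODE
    systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
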