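Package: kcnqsim
Title: Allosteric Gating Model Simulation and Voltage-Clamp-Fluorometry
    Analysis for KCNQ1 Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time Markov modelling of KCNQ1 channel gating with a
    12-state allosteric scheme (four independent voltage sensors with resting,
    intermediate and concerted-activated configurations, each coupled to a
    closed/open pore). Simulates two-electrode voltage-clamp and
    voltage-clamp-fluorometry observables under piecewise-constant voltage
    protocols by exact matrix-exponential propagation, extracts the standard
    measurement quantities (single-exponential tail time constants, half-decay
    times, isochronal G(V) and F(V) curves with Boltzmann fits), models drug
    perturbations as multiplicative scalings of rate classes (pore-slowing
    versus voltage-sensor-slowing mechanisms), generates synthetic noisy
    paired control/drug recordings with between-cell variability, and recovers
    perturbation factors from such recordings by weighted least squares with
    information-criterion model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
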