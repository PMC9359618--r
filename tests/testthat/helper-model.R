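# Shared fixtures, all built in code.

# random but valid parameter sets around the calibrated defaults
random_params <- function(n = 1, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- default_params()
    for (f in c("alpha0", "beta0", "theta0", "eta0", "ko0", "kc0"))
      p[[f]] <- p[[f]] * exp(stats::runif(1, -0.7, 0.7))
    p$L <- 1 + stats::runif(1, 0, 4)
    p$D <- 1 + stats::runif(1, 0, 10)
    p$x_split <- stats::runif(1)
    for (f in c("z_alpha", "z_beta", "z_theta", "z_eta"))
      p[[f]] <- p[[f]] * stats::runif(1, 0.6, 1.4)
    validate_params(p)
    p
  })
}

# two-state generator: closed -> open at rate a, open -> closed at rate b
two_state_Q <- function(a = 2, b = 3) {
  matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE,
         dimnames = list(c("closed", "open"), c("closed", "open")))
}

# tail fit of segment k of a standard three-segment trace
tail_tau <- function(trace, channel, k = 3L) {
  kcnqsim:::segment_relaxation_fit(trace, k, channel, direction = "auto")$tau
}

# quick percent changes in tail taus for a perturbation, two-pulse only
quick_dtau <- function(params, pert, dt_s = 2e-3) {
  proto <- two_pulse_protocol(dt_s = dt_s)
  ctrl <- simulate_trace(params, proto, fluor = "raw", keep_states = FALSE)
  drug <- simulate_trace(params, proto, perturbation = pert, fluor = "raw",
                         keep_states = FALSE)
  c(dtau_I = percent_change(tail_tau(ctrl, "current"),
                            tail_tau(drug, "current")),
    dtau_F = percent_change(tail_tau(ctrl, "fluorescence"),
                            tail_tau(drug, "fluorescence")))
}
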