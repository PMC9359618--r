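test_that("standard protocols match the recording conventions", {
  tp <- two_pulse_protocol()
  expect_equal(tp$hold_mV, -80)
  expect_equal(tail(tp$segments$voltage_mV, 2), c(20, -120))
  expect_equal(tail(tp$segments$duration_s, 2), c(2, 2))
  fam <- activation_family()
  expect_length(fam, 12)
  v <- vapply(fam, function(pr) pr$segments$voltage_mV[2], 0)
  expect_equal(v, seq(-140, 80, by = 20))
  expect_true(all(vapply(fam, function(pr) pr$hold_mV, 0) == -80))
  expect_true(all(vapply(fam, function(pr) pr$segments$voltage_mV[3], 0) ==
                    -120))
})

test_that("protocol validation rejects bad segments and sample intervals", {
  expect_error(voltage_protocol(data.frame(duration_s = -1, voltage_mV = 0)),
               "positive")
  expect_error(voltage_protocol(data.frame(duration_s = 1, voltage_mV = 0),
                                dt_s = 2), "dt_s")
  expect_error(voltage_protocol(data.frame(duration_s = 0.0105,
                                           voltage_mV = 0), dt_s = 1e-2),
               "integer multiples")
})

test_that("a trace started at its own steady state stays there", {
  p <- default_params()
  proto <- voltage_protocol(data.frame(duration_s = 1, voltage_mV = -80),
                            hold_mV = -80, dt_s = 5e-3)
  tr <- simulate_trace(p, proto)
  occ <- as.matrix(tr[, paste0("p_", state_names())])
  expect_lt(max(abs(sweep(occ, 2, occ[1, ]))), 1e-9)
  expect_lt(max(abs(diff(tr$current))), 1e-9 * max(abs(tr$current)))
})

test_that("two-state relaxation recovers the closed-form time constant", {
  # step from pure closed; relaxation rate a + b = 5/s -> tau = 0.2 s
  prop <- kcnqsim:::propagate_piecewise(list(two_state_Q(2, 3)), 2,
                                        c(1, 0), 1e-3)
  fit <- fit_single_exponential(prop$time, prop$occ[, 2], direction = "rise")
  expect_equal(fit$tau, 0.2, tolerance = 5e-3)
  expect_lt(fit$rms, 1e-10)
})

test_that("occupancies are conserved and propagation is grid-independent", {
  p <- default_params()
  tr1 <- simulate_trace(p, two_pulse_protocol(dt_s = 1e-3))
  expect_lte(attr(tr1, "drift"), 1e-9)
  occ <- as.matrix(tr1[, paste0("p_", state_names())])
  expect_gte(min(occ), -1e-12)
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
  # exact per-segment propagation: halving dt leaves shared samples unchanged
  tr2 <- simulate_trace(p, two_pulse_protocol(dt_s = 2e-3))
  common <- match(round(tr2$time_s, 9), round(tr1$time_s, 9))
  expect_equal(tr2$current, tr1$current[common], tolerance = 1e-8)
  expect_equal(tr2$fluorescence, tr1$fluorescence[common], tolerance = 1e-8)
})

test_that("the identity perturbation is bit-identical to no perturbation", {
  p <- default_params()
  proto <- two_pulse_protocol(dt_s = 5e-3)
  a <- simulate_trace(p, proto)
  b <- simulate_trace(p, proto, perturbation = identity_perturbation())
  expect_identical(a$current, b$current)
  expect_identical(a$fluorescence, b$fluorescence)
})

test_that("current rises during depolarization and decays during the tail", {
  tr <- simulate_trace(default_params(), two_pulse_protocol(dt_s = 1e-3),
                       keep_states = FALSE)
  # oracle: sign of the numerical derivative, skipping 10 ms after each step
  dep <- tr$time_s > 0.21 & tr$time_s < 2.2 - 1e-9
  expect_true(all(diff(tr$current[dep]) > 0))
  tail_seg <- tr$time_s > 2.21
  expect_true(all(diff(abs(tr$current[tail_seg])) < 0))
})

test_that("trace files round-trip through the text format", {
  tr <- simulate_trace(default_params(), two_pulse_protocol(dt_s = 1e-2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path, states = TRUE)
  back <- read_trace(path)
  expect_equal(back$current, tr$current, tolerance = 1e-12)
  expect_equal(back$fluorescence, tr$fluorescence, tolerance = 1e-12)
  expect_equal(back$p_OA, tr$p_OA, tolerance = 1e-12)
  # writing the re-read trace reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_trace(back, path2, states = TRUE)
  expect_identical(readLines(path), readLines(path2))
})

test_that("fluorescence normalization conventions behave as documented", {
  p <- default_params()
  proto <- two_pulse_protocol(dt_s = 5e-3)
  raw <- simulate_trace(p, proto, fluor = "raw", keep_states = FALSE)
  norm <- simulate_trace(p, proto, fluor = "normalized", keep_states = FALSE)
  expect_equal(range(norm$fluorescence), c(0, 1), tolerance = 1e-12)
  sc <- attr(norm, "fluor_scale")
  expect_equal((raw$fluorescence - sc[1]) / diff(sc), norm$fluorescence,
               tolerance = 1e-12)
  # paired display: the drug trace reuses the control's scale
  drug <- simulate_trace(p, proto, perturbation = rl3_perturbation(),
                         fluor = "normalized", fluor_scale = sc,
                         keep_states = FALSE)
  expect_gt(max(drug$fluorescence), 1)  # drug F exceeds the control range
})
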