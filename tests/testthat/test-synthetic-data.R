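test_that("zero recording noise reproduces the simulator output exactly", {
  tr <- simulate_trace(default_params(), two_pulse_protocol(dt_s = 5e-3),
                       fluor = "raw", keep_states = FALSE)
  nm0 <- noise_model(sigma_I = 0, sigma_F = 0)
  noisy <- generate_noisy_trace(tr, nm0, seed = 1)
  expect_identical(noisy$current, tr$current)
  expect_identical(noisy$fluorescence, tr$fluorescence)
})

test_that("noise generation honours the seeding contract", {
  tr <- simulate_trace(default_params(), two_pulse_protocol(dt_s = 5e-3),
                       fluor = "raw", keep_states = FALSE)
  nm <- noise_model()
  a <- generate_noisy_trace(tr, nm, seed = 7)
  b <- generate_noisy_trace(tr, nm, seed = 7)
  c <- generate_noisy_trace(tr, nm, seed = 8)
  expect_identical(a$current, b$current)
  expect_false(identical(a$current, c$current))
  # byte-identical files from the same seed
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_trace(a, fa); write_trace(b, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
})

test_that("applied noise has the requested standard deviation", {
  tr <- simulate_trace(default_params(), two_pulse_protocol(dt_s = 1e-3),
                       fluor = "raw", keep_states = FALSE)
  nm <- noise_model(sigma_I = 0.02, sigma_F = 0.02)
  noisy <- generate_noisy_trace(tr, nm, seed = 5)
  resid <- noisy$current - tr$current
  expect_equal(stats::sd(resid), 0.02 * max(abs(tr$current)),
               tolerance = 0.05)
  expect_error(noise_model(sigma_I = -0.1), ">= 0")
})

test_that("the manifest stores the exact truth of every cell", {
  preset <- get_preset("rl3_pswt", n_cells = 3)
  dir <- withr::local_tempdir()
  x <- generate_experiment(preset, seed = 11, dir = dir, dt_s = 5e-3,
                           include_family = FALSE)
  y <- load_experiment(dir)
  expect_length(y$cells, 3)
  # re-simulating from manifest parameters with zero noise reproduces the
  # stored noiseless traces bit for bit
  proto <- two_pulse_protocol(dt_s = 5e-3)
  for (i in 1:3) {
    p_ctrl <- y$cells[[i]]$params
    p_ctrl$Gmax <- p_ctrl$Gmax * y$cells[[i]]$g_ctrl
    resim <- simulate_trace(p_ctrl, proto, fluor = "raw", keep_states = FALSE)
    stored <- file.path(dir, paste0(y$cells[[i]]$id,
                                    "_ctrl_pulse_noiseless.tsv"))
    rewrit <- withr::local_tempfile()
    write_trace(resim, rewrit)
    expect_identical(unname(tools::md5sum(rewrit)),
                     unname(tools::md5sum(stored)))
  }
  # the noisy traces round-trip through the reader at file precision
  expect_equal(y$cells[[1]]$ctrl_pulse$current,
               x$cells[[1]]$ctrl_pulse$current, tolerance = 1e-10)
})

test_that("an identity-perturbation experiment shows no drug effect", {
  preset <- get_preset("null_pswt", n_cells = 3)
  x <- generate_experiment(preset, seed = 3, dt_s = 5e-3,
                           include_family = FALSE)
  s <- analyze_experiment(x)
  # amplitude factors differ between the paired recordings, so dI scatters
  # with the amplitude CV; the tau changes only with recording noise
  expect_lt(abs(s$mean["dI_pct"]), 3 * 100 * 0.12 * sqrt(2) / sqrt(3))
  expect_lt(abs(s$mean["dtau_I_pct"]), 10)
  expect_lt(abs(s$mean["dtau_F_pct"]), 10)
})

test_that("doubling the amplitude CV doubles the dispersion of the amplitude effect", {
  sd_of <- function(cv, seeds) {
    vapply(seeds, function(sd) {
      preset <- experiment_preset("disp", perturbation = rl3_perturbation(),
                                  n_cells = 8,
                                  noise = noise_model(sigma_I = 0, sigma_F = 0,
                                                      amplitude_cv = cv,
                                                      rate_cv = 0))
      x <- generate_experiment(preset, seed = sd, dt_s = 1e-2,
                               include_family = FALSE)
      stats::sd(analyze_experiment(x)$per_cell$dI_pct)
    }, 0)
  }
  seeds <- 101:112
  ratio <- mean(sd_of(0.12, seeds)) / mean(sd_of(0.06, seeds))
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})
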