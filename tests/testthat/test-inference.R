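pure_vsd_preset <- function(n_cells = 3, noise = noise_model(),
                            s_vsd = 1 / 3.4, s_cond = 1) {
  experiment_preset("vsd_gen",
                    perturbation = drug_perturbation("vsd",
                                                     s_vsd_deact = s_vsd,
                                                     s_conductance = s_cond),
                    n_cells = n_cells, noise = noise)
}

noiseless <- function() noise_model(sigma_I = 0, sigma_F = 0,
                                    amplitude_cv = 0, rate_cv = 0)

test_that("a single free factor is recovered exactly from noiseless data", {
  x <- generate_experiment(pure_vsd_preset(noise = noiseless()), seed = 2,
                           dt_s = 5e-3, include_family = FALSE)
  res <- recover_perturbation(x, free = "s_vsd_deact", dt_fit = 5e-3,
                              n_starts = 2)
  expect_equal(unname(res$estimate), 1 / 3.4, tolerance = 1e-4)
  expect_true(res$converged)
})

test_that("the noiseless objective has a unique minimum at the truth", {
  x <- generate_experiment(pure_vsd_preset(n_cells = 3, noise = noiseless()),
                           seed = 4, dt_s = 5e-3, include_family = FALSE)
  f <- kcnqsim:::cell_objective_env(x$cells[[1]], 5e-3, 1e-2,
                                    c("current", "fluorescence"))
  grid <- seq(-2.5, 2.5, by = 0.5) + log(1 / 3.4)
  vals <- vapply(grid, function(th)
    f(kcnqsim:::pert_from_theta(th, "s_vsd_deact")), 0)
  i0 <- which.min(vals)
  expect_equal(grid[i0], log(1 / 3.4), tolerance = 1e-9)
  expect_true(all(diff(vals[1:i0]) < 0))
  expect_true(all(diff(vals[i0:length(vals)]) > 0))
})

test_that("control-vs-control data recover the identity perturbation", {
  preset <- experiment_preset("null", perturbation = identity_perturbation(),
                              n_cells = 3,
                              noise = noise_model(amplitude_cv = 0))
  x <- generate_experiment(preset, seed = 6, dt_s = 5e-3,
                           include_family = FALSE)
  res <- recover_perturbation(x, free = c("s_vsd_deact", "s_conductance"),
                              dt_fit = 1e-2, n_starts = 3)
  expect_equal(unname(res$estimate["s_vsd_deact"]), 1, tolerance = 0.05)
  expect_equal(unname(res$estimate["s_conductance"]), 1, tolerance = 0.05)
})

test_that("recovery warns about degenerate factor selections", {
  x <- generate_experiment(pure_vsd_preset(noise = noiseless()), seed = 2,
                           dt_s = 5e-3, include_family = FALSE)
  expect_warning(
    recover_perturbation(x, free = c("s_pore_open", "s_pore_close",
                                     "s_vsd_deact"),
                         channels = "current", dt_fit = 1e-2, n_starts = 1),
    "fluorescence")
})

test_that("recovery error shrinks with the number of cells", {
  est_for <- function(n_cells, seeds) {
    vapply(seeds, function(sd) {
      x <- generate_experiment(pure_vsd_preset(n_cells = n_cells), seed = sd,
                               dt_s = 5e-3, include_family = FALSE)
      res <- recover_perturbation(x, free = "s_vsd_deact", dt_fit = 1e-2,
                                  n_starts = 2)
      unname(res$estimate)
    }, 0)
  }
  seeds <- 201:206
  sd_small <- stats::sd(log(est_for(5, seeds)))
  sd_large <- stats::sd(log(est_for(20, seeds)))
  expect_lt(sd_large, sd_small)
})

test_that("model selection identifies the generating mechanism", {
  pore_preset <- experiment_preset(
    "pore_gen",
    perturbation = drug_perturbation("pore", s_pore_open = 1 / 7,
                                     s_pore_close = 1 / 7,
                                     s_conductance = 1.5),
    n_cells = 3)
  xp <- generate_experiment(pore_preset, seed = 9, dt_s = 5e-3,
                            include_family = FALSE)
  sel_p <- model_selection(xp, dt_fit = 1e-2, n_starts = 2)
  expect_identical(sel_p$selected, "pore")

  xv <- generate_experiment(pure_vsd_preset(s_cond = 1.24), seed = 9,
                            dt_s = 5e-3, include_family = FALSE)
  sel_v <- model_selection(xv, dt_fit = 1e-2, n_starts = 2)
  expect_identical(sel_v$selected, "vsd")

  x0 <- generate_experiment(
    experiment_preset("null", perturbation = identity_perturbation(),
                      n_cells = 3), seed = 9, dt_s = 5e-3,
    include_family = FALSE)
  sel_0 <- model_selection(x0, dt_fit = 1e-2, n_starts = 2)
  expect_identical(sel_0$selected, "indistinguishable")
})
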