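test_that("rate matrices are conservative generators with the scheme's topology", {
  sets <- random_params(8, seed = 11)
  set.seed(12)
  for (p in sets) {
    V <- stats::runif(1, -160, 80)
    Q <- build_rate_matrix(p, V)
    expect_lt(max(abs(rowSums(Q))), 1e-12 * max(abs(Q)))
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
    # non-adjacent states carry exactly zero rate
    expect_identical(Q["C0", "C2"], 0)
    expect_identical(Q["C0", "O3"], 0)
    expect_identical(Q["C1", "OA"], 0)
    expect_identical(Q["CA", "O4"], 0)
  }
})

test_that("voltage moves forward and backward rates in opposite directions", {
  p <- default_params()
  Q1 <- build_rate_matrix(p, -60)
  Q2 <- build_rate_matrix(p, -20)
  expect_gt(Q2["C0", "C1"], Q1["C0", "C1"])  # alpha rises with V
  expect_gt(Q2["C4", "CA"], Q1["C4", "CA"])  # theta rises with V
  expect_lt(Q2["C1", "C0"], Q1["C1", "C0"])  # beta falls with V
  expect_lt(Q2["CA", "C4"], Q1["CA", "C4"])  # eta falls with V
})

test_that("every constructed parameter set satisfies microscopic reversibility", {
  for (p in random_params(6, seed = 21)) {
    rep <- thermodynamic_consistency(p, V = -80)
    expect_true(attr(rep, "pass"))
    expect_equal(rep$ratio, rep(1, 5), tolerance = 1e-10)
  }
  # the split only redistributes L between forward and backward open-tier rates
  for (x in c(0, 1)) {
    p <- default_params(); p$x_split <- x
    expect_true(attr(thermodynamic_consistency(p), "pass"))
  }
})

test_that("a broken detailed-balance split is flagged on the right loop", {
  Q <- build_rate_matrix(default_params(), -80)
  Q["O2", "O1"] <- Q["O2", "O1"] * 1.7  # tamper one open-tier backward rate
  rep <- thermodynamic_consistency(Q)
  expect_false(attr(rep, "pass"))
  expect_false(rep$pass[rep$loop == "C1-C2-O2-O1"])
  expect_true(all(rep$pass[rep$loop != "C1-C2-O2-O1"]))
})

test_that("closed-tier equilibrium is binomial when the pore is decoupled", {
  p <- default_params()
  p$L <- 1; p$D <- 1
  # voltage where alpha(V) = beta(V): binomial(4, 1/2)
  v_half <- p$VT * log(p$beta0 / p$alpha0) / (p$z_alpha + p$z_beta)
  for (V in c(v_half, -60, -20)) {
    Q <- build_rate_matrix(p, V)
    # oracle: null space of the 5-state closed-tier sub-generator
    sub <- Q[1:5, 1:5]
    diag(sub) <- 0
    diag(sub) <- -rowSums(sub)
    ns <- qr.solve(rbind(t(sub), rep(1, 5)), c(rep(0, 5), 1))
    a <- p$alpha0 * exp(p$z_alpha * V / p$VT)
    b <- p$beta0 * exp(-p$z_beta * V / p$VT)
    expect_equal(ns, stats::dbinom(0:4, 4, a / (a + b)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("steady state solves p Q = 0 and matches long-time propagation", {
  p <- default_params()
  Q <- build_rate_matrix(p, -40)
  ss <- steady_state(Q)
  expect_equal(sum(ss), 1, tolerance = 1e-12)
  expect_gte(min(ss), -1e-14)
  expect_lt(max(abs(ss %*% Q)), 1e-10)
  # oracle: matrix-exponential propagation from a point mass
  rates <- abs(Q[Q != 0])
  Tlong <- 200 / min(rates)
  p0 <- c(1, rep(0, 11))
  pT <- as.numeric(p0 %*% as.matrix(Matrix::expm(Q * Tlong)))
  expect_equal(unname(ss), pT, tolerance = 1e-8)
})

test_that("two-state reduction gives the closed-form open fraction", {
  ss <- steady_state(two_state_Q(a = 2, b = 3))
  expect_equal(unname(ss["open"]), 0.4, tolerance = 1e-12)
})

test_that("invalid parameters are rejected with the offending field named", {
  p <- default_params()
  p$beta0 <- -1
  expect_error(validate_params(p), "beta0")
  p <- default_params(); p$L <- 0.5
  expect_error(validate_params(p), "'L'")
  p <- default_params(); p$w_A <- 0.1  # below w_I
  expect_error(validate_params(p), "w_A")
  p <- default_params(); p$x_split <- 1.5
  expect_error(validate_params(p), "x_split")
  expect_error(build_rate_matrix(default_params(), Inf), "'V'")
})

test_that("parameter files round-trip losslessly at 12 significant digits", {
  p <- default_params()
  p$alpha0 <- 123.456789012
  path <- withr::local_tempfile(fileext = ".cfg")
  write_params(p, path, comment = "round-trip check")
  q <- read_params(path)
  for (f in kcnqsim:::param_fields)
    expect_equal(q[[f]], p[[f]], tolerance = 1e-12)
  # a second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".cfg")
  write_params(q, path2, comment = "round-trip check")
  expect_identical(readLines(path), readLines(path2))
  expect_error(read_params(withr::local_tempfile()), "not found")
})

test_that("the shipped default configuration matches default_params()", {
  cfg <- system.file("extdata", "default_params.cfg", package = "kcnqsim")
  expect_true(nzchar(cfg))
  p <- read_params(cfg)
  expect_equal(unclass(p)[kcnqsim:::param_fields],
               unclass(default_params())[kcnqsim:::param_fields],
               tolerance = 1e-12)
})
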