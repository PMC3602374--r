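dose_625 <- 30000 * 6.02214076e-3 * 2e-6

test_that("closure law matches the one-hit closed form at p = 0", {
  expect_equal(closure_fraction(400, 0), 0)
  expect_equal(closure_fraction(400, log(2) / 400), 0.5, tolerance = 1e-12)
  doses <- seq(0, 0.02, length.out = 50)
  for (sigma in c(50, 381, 800)) {
    expect_equal(closure_fraction(sigma, doses),
                 1 - exp(-sigma * doses), tolerance = 1e-12)
  }
})

test_that("connectivity closure is continuous at p -> 0 and monotone", {
  doses <- dose_625 * 1:40
  c_p0 <- closure_fraction(381, doses, p = 0)
  c_eps <- closure_fraction(381, doses, p = 1e-10)
  expect_equal(c_eps, c_p0, tolerance = 1e-8)

  c_p <- closure_fraction(381, doses, p = 0.3)
  expect_true(all(diff(c_p) > 0))
  # connectivity accelerates closure relative to p = 0
  expect_true(all(c_p >= c_p0))
  # monotone in sigma too
  expect_true(all(closure_fraction(500, doses, p = 0.3) >= c_p))
})

test_that("connectivity closure agrees with a fine-step ODE oracle", {
  skip_if_not_installed("deSolve")
  doses <- dose_625 * 1:10
  for (p in c(0.15, 0.3, 0.6)) {
    ours <- closure_fraction(400, doses, p = p)
    oracle <- deSolve::lsoda(
      y = c(C = 0),
      times = c(0, doses),
      func = function(D, y, parms) list(400 * (1 - y[1]) / (1 - p * y[1])),
      rtol = 1e-12, atol = 1e-14
    )[-1, "C"]
    expect_equal(ours, unname(oracle), tolerance = 1e-6)
  }
})

test_that("fluorescence map interpolates Fo to Fm for any connectivity", {
  for (p in c(0, 0.3, 0.7)) {
    pars <- induction_params(1, 3, 381, p = p)
    expect_equal(model_fluorescence(pars, 0), 1)
    expect_equal(model_fluorescence(pars, 1), 3)
  }
  expect_equal(model_fluorescence(induction_params(1, 3, 381), 0.5), 2.0)
  # connectivity makes the rise sigmoidal: below the linear map mid-rise
  pars_p <- induction_params(1, 3, 381, p = 0.5)
  expect_lt(model_fluorescence(pars_p, 0.5), 2.0)
})

test_that("noiseless dark fits recover generating parameters", {
  cases <- list(
    list(sigma = 381, wl = 625),  # red-light cross-sections are large
    list(sigma = 71, wl = 455)    # blue-light cross-sections are small
  )
  for (cs in cases) {
    pr <- flashlet_protocol(wavelength_nm = cs$wl)
    tr <- simulate_frr_transient(induction_params(1, 3, cs$sigma), pr)
    fit <- fit_dark_transient(tr)
    expect_true(fit$converged)
    expect_lt(abs(fit$sigma - cs$sigma), 0.1)
    expect_lt(abs(fit$FvFm - 2 / 3), 1e-4)
  }
})

test_that("noiseless recovery holds across a wide sigma grid", {
  pr <- flashlet_protocol()
  for (sigma in c(50, 100, 200, 400, 800)) {
    tr <- simulate_frr_transient(induction_params(1, 3, sigma), pr)
    fit <- fit_dark_transient(tr)
    expect_lt(abs(fit$sigma - sigma) / sigma, 1e-3)
  }
})

test_that("sigma and Fv/Fm are invariant under fluorescence rescaling", {
  tr <- simulate_frr_transient(induction_params(1, 3, 381),
                               noise_sd = 0.02, seed = 11)
  scaled <- frr_transient(tr$times_us, 7.3 * tr$values, tr$protocol)
  f1 <- fit_dark_transient(tr)
  f2 <- fit_dark_transient(scaled)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-6)
  expect_equal(f2$FvFm, f1$FvFm, tolerance = 1e-6)
})

test_that("flat non-monotone records are rejected as insufficient signal", {
  # alternating jitter with no net rise: range below 3x the residual scale
  vals <- 2 + 0.01 * rep(c(0, 1), 20)
  tr <- frr_transient(4 * (1:40) - 2, vals, flashlet_protocol())
  expect_error(fit_dark_transient(tr), "insufficient variable fluorescence")
})

test_that("dark fitting needs at least 10 flashlets", {
  pr <- flashlet_protocol(n_flashlets = 8)
  tr <- simulate_frr_transient(induction_params(1, 3, 381), pr)
  expect_error(fit_dark_transient(tr), "10 flashlets")
})

test_that("light-step derived quantities follow their definitions", {
  # Fm' = 2.0, Fs = 1.4, Fo_dark = 1.0 -> qP = 0.6, Phi_PSII = 0.3
  tr <- simulate_light_step(induction_params(1, 3, 381, C0 = 0.4),
                            Fm_prime = 2.0)
  fit <- fit_light_transient(tr, Fo_dark = 1.0)
  expect_equal(fit$qP, 0.6, tolerance = 1e-3)
  expect_equal(fit$Phi_PSII, 0.3, tolerance = 1e-3)

  # Fs = Fo_dark -> all centres open -> qP = 1
  tr2 <- simulate_frr_transient(induction_params(1, 3, 381))
  fit2 <- fit_light_transient(tr2, Fo_dark = 1.0)
  expect_equal(fit2$qP, 1, tolerance = 1e-6)
})

test_that("qP is clipped with a warning when Fs drops below dark Fo", {
  # strong quenching: Fm' pulled down so far that the baseline sits
  # below the dark Fo proxy
  tr <- simulate_light_step(induction_params(1, 3, 381, C0 = 0.05),
                            Fm_prime = 1.3)
  expect_warning(fit <- fit_light_transient(tr, Fo_dark = 1.2), "clipped")
  expect_lte(fit$qP, 1)
  expect_gte(fit$qP, 0)
})

test_that("noisy sigma recovery is close to the information bound", {
  # at additive noise sd 0.04 (2% of Fv here) the Cramer-Rao bound for
  # this 40-flashlet design puts the relative sd of sigma-hat at 3.25%,
  # i.e. a median absolute error of about 2.2%; the least-squares fit
  # should sit near that bound, not above 3%
  errs <- vapply(1:200, function(s) {
    tr <- simulate_frr_transient(induction_params(1, 3, 381),
                                 noise_sd = 0.04, seed = s)
    abs(fit_dark_transient(tr)$sigma - 381) / 381
  }, numeric(1))
  expect_lt(median(errs), 0.03)
  # and at half that noise the median error drops below 2%
  errs2 <- vapply(1:200, function(s) {
    tr <- simulate_frr_transient(induction_params(1, 3, 381),
                                 noise_sd = 0.02, seed = s)
    abs(fit_dark_transient(tr)$sigma - 381) / 381
  }, numeric(1))
  expect_lt(median(errs2), 0.02)
})
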