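# dose per flashlet of the default 625 nm protocol, photons A^-2
dose_625 <- 30000 * 6.02214076e-3 * 2e-6

test_that("dark transient follows the closure model flashlet by flashlet", {
  pars <- induction_params(Fo = 1, Fm = 3, sigma = 381)
  tr <- simulate_frr_transient(pars, flashlet_protocol())

  expect_length(tr$values, 40)
  expect_equal(tr$values[1], 1 + 2 * (1 - exp(-381 * dose_625)),
               tolerance = 1e-12)
  # noiseless output is non-decreasing and bounded by Fo, Fm
  expect_true(all(diff(tr$values) >= 0))
  expect_true(all(tr$values >= 1 & tr$values <= 3))
})

test_that("transient saturates to Fm once the cumulative dose is large", {
  # sigma * D_total >= 5 puts the last flashlet within 1% of Fm
  pars <- induction_params(Fo = 1, Fm = 3, sigma = 5 / (40 * dose_625))
  tr <- simulate_frr_transient(pars, flashlet_protocol())
  expect_lt(abs(tr$values[40] - 3) / 3, 0.01)
})

test_that("zero cross-section gives a flat record at Fo", {
  pars <- induction_params(Fo = 1, Fm = 3, sigma = 0, .relax = TRUE)
  tr <- simulate_frr_transient(pars, flashlet_protocol())
  expect_equal(tr$values, rep(1, 40))
})

test_that("generators are deterministic given a seed", {
  pars <- induction_params(1, 3, 381)
  a <- simulate_frr_transient(pars, noise_sd = 0.05, seed = 7)
  b <- simulate_frr_transient(pars, noise_sd = 0.05, seed = 7)
  c <- simulate_frr_transient(pars, noise_sd = 0.05, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))

  g1 <- simulate_growth_series(0.019, 0.1, 72, noise_sd = 0.02, seed = 3)
  g2 <- simulate_growth_series(0.019, 0.1, 72, noise_sd = 0.02, seed = 3)
  expect_identical(g1, g2)

  b1 <- simulate_blot(c(5, 25, 125), 100, noise_cv = 0.05, seed = 4)
  b2 <- simulate_blot(c(5, 25, 125), 100, noise_cv = 0.05, seed = 4)
  expect_identical(b1, b2)

  p1 <- simulate_pe_dataset(96, 90, noise_sd = 3, seed = 5)
  p2 <- simulate_pe_dataset(96, 90, noise_sd = 3, seed = 5)
  expect_identical(p1, p2)
})

test_that("invalid parameters and protocols are rejected", {
  expect_error(induction_params(1, 3, 381, C0 = 1), "C0")
  expect_error(induction_params(1, 0.5, 381), "Fm")
  expect_error(induction_params(1, 3, -5), "sigma")
  # a train reaching 1000 us enters the re-opening regime
  expect_error(flashlet_protocol(n_flashlets = 250), "1000 us")
  expect_error(simulate_blot(c(5, 25), 100), "3 standard")
  expect_error(simulate_blot(c(5, 5, 5), 100), "identical")
})

test_that("light-step generator reduces to the dark generator at C0 = 0", {
  pars <- induction_params(1, 3, 381, C0 = 0)
  dark <- simulate_frr_transient(pars)
  light <- simulate_light_step(pars, Fm_prime = 3)
  expect_equal(light$values, dark$values, tolerance = 1e-12)
})

test_that("light-step baseline and ground-truth qP follow from C0 and Fm'", {
  # Fo = 1, Fm' = 2, C0 = 0.4 -> Fs = 1.4 and true qP = 0.6
  pars <- induction_params(1, 3, 381, C0 = 0.4)
  tr <- simulate_light_step(pars, Fm_prime = 2)
  Fs <- 1 + (2 - 1) * 0.4
  # the first measured value is one flashlet dose past the Fs baseline
  expect_equal(tr$values[1],
               1 + (2 - 1) * closure_fraction(381, dose_625, C0 = 0.4),
               tolerance = 1e-12)
  expect_true(all(tr$values > Fs))
  expect_equal((2 - Fs) / (2 - 1), 0.6)
})

test_that("noiseless light-step fit recovers sigma' to 1e-4 relative", {
  pars <- induction_params(1, 3, 300, C0 = 0.35)
  tr <- simulate_light_step(pars, Fm_prime = 2.4)
  fit <- fit_light_transient(tr, Fo_dark = 1)
  expect_lt(abs(fit$sigma_prime - 300) / 300, 1e-4)
})

test_that("growth series is exactly exponential before onset", {
  d <- simulate_growth_series(0.019, 0.1, onset_h = 72,
                              times_h = seq(0, 72, 12))
  slopes <- diff(log(d$a750)) / diff(d$time_h)
  expect_equal(slopes, rep(0.019, 6), tolerance = 1e-12)

  flat <- simulate_growth_series(0, 0.1, 72, times_h = seq(0, 120, 24))
  expect_equal(flat$a750, rep(0.1, 6), tolerance = 1e-12)
})

test_that("growth slows but does not reverse after onset", {
  d <- simulate_growth_series(0.019, 0.1, onset_h = 72,
                              times_h = seq(0, 120, 12))
  lnA <- log(d$a750)
  expect_true(all(diff(lnA) > 0))
  inc <- diff(lnA)
  expect_lt(inc[length(inc)], inc[1]) # post-onset increments shrink
})

test_that("noiseless blot round-trips the true abundance", {
  for (truth in c(100, 662)) {
    blot <- simulate_blot(c(0.1, 0.5, 1, 2) * truth, truth, ug_loaded = 1)
    expect_equal(quantify_blot(blot), truth, tolerance = 1e-9)
  }
})

test_that("P-E generator hits the tanh anchors", {
  d <- simulate_pe_dataset(96, 90, irradiances = c(0, 90, 400))
  expect_equal(d$etr[1], 0)
  expect_equal(d$etr[2], 96 * tanh(1), tolerance = 1e-12)
})

test_that("noisy transient values stay within 5 noise SDs of [Fo, Fm]", {
  pars <- induction_params(1, 3, 381)
  sd <- 0.04
  vals <- unlist(lapply(1:200, function(s) {
    simulate_frr_transient(pars, noise_sd = sd, seed = s)$values
  }))
  inside <- mean(vals >= 1 - 5 * sd & vals <= 3 + 5 * sd)
  expect_gte(inside, 0.9999)
})
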