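test_that("pure dark state decomposes to s = 1 with a null photoproduct", {
  sc <- default_equilibrium_scenario("pcb", f = 1, noise_sigma = 0)
  eq <- simulate_equilibrium(sc)
  d <- determine_subtraction_factor(eq$S_equil, eq$S_dark, 649,
                                    noise_floor = 0)
  expect_equal(d$s, 1, tolerance = 1e-12)
  expect_lt(max(abs(d$S_phot$values)), 1e-12)
})

test_that("noiseless mixtures recover the dark fraction exactly", {
  # a photoproduct that is exactly transparent at the marker (far tails
  # clipped below double precision noise)
  wl <- seq(450, 800, by = 2)
  for (case in list(list(f = 0.22, marker = 649, dark_q = 649, phot_q = 545),
                    list(f = 0.35, marker = 697, dark_q = 697, phot_q = 600))) {
    dark <- gaussian_spectrum(gaussian_band(case$dark_q, 50, 0.5), wl)$values
    phot <- gaussian_spectrum(gaussian_band(case$phot_q, 55, 0.4), wl)$values
    phot[phot < 1e-4] <- 0
    stopifnot(phot[which.min(abs(wl - case$marker))] == 0)
    S_dark <- spectrum(wl, dark)
    S_equil <- spectrum(wl, case$f * dark + (1 - case$f) * phot)
    d <- determine_subtraction_factor(S_equil, S_dark, case$marker,
                                      noise_floor = 0)
    expect_equal(d$s, case$f, tolerance = 1e-9)
    expect_false(d$constrained)
    expect_equal(d$S_phot$values, (1 - case$f) * phot, tolerance = 1e-9)
  }

  # default scenarios: the photoproduct's far Gaussian tail at the marker
  # is below the noise floor; noiseless recovery is exact to grid resolution
  for (ch in c("pcb", "bv")) {
    sc <- default_equilibrium_scenario(ch, noise_sigma = 0)
    eq <- simulate_equilibrium(sc)
    d <- determine_subtraction_factor(eq$S_equil, eq$S_dark,
                                      sc$marker_wavelength, noise_floor = 0)
    expect_lt(abs(d$s - sc$f), 0.005 + 1e-9)
  }
})

test_that("noisy recovery stays within 0.02 over 20 seeded replicates", {
  errs <- vapply(1:20, function(i) {
    sc <- default_equilibrium_scenario("pcb", seed = 400 + i)
    eq <- simulate_equilibrium(sc)
    d <- determine_subtraction_factor(eq$S_equil, eq$S_dark, 649,
                                      noise_floor = 2 * sc$noise_sigma)
    abs(d$s - sc$f)
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("recovered s increases with the generated dark fraction", {
  ss <- vapply(c(0.1, 0.22, 0.35, 0.5, 0.7), function(f) {
    sc <- default_equilibrium_scenario("pcb", f = f, seed = 77)
    eq <- simulate_equilibrium(sc)
    determine_subtraction_factor(eq$S_equil, eq$S_dark, 649,
                                 noise_floor = 2 * sc$noise_sigma)$s
  }, numeric(1))
  expect_true(all(diff(ss) > 0))
})

test_that("a photoproduct absorbing at the marker triggers the constraint", {
  # photoproduct deliberately non-transparent at 649 nm
  wl <- seq(450, 800, by = 2)
  dark <- gaussian_spectrum(gaussian_band(649, 50, 0.5), wl)$values
  phot <- gaussian_spectrum(list(gaussian_band(545, 55, 0.4),
                                 gaussian_band(640, 40, 0.12)), wl)$values
  f <- 0.3
  S_dark <- spectrum(wl, dark)
  S_equil <- spectrum(wl, f * dark + (1 - f) * phot)
  d <- determine_subtraction_factor(S_equil, S_dark, 649, noise_floor = 1e-4)
  expect_true(d$constrained)
  expect_lt(d$s, d$s0)
  expect_gt(d$s0, f) # marker nulling over-subtracts
  # brute-force scan oracle: largest s on the same grid meeting the
  # negativity bound
  cand <- seq(d$s0, 0, by = -0.005)
  ok <- vapply(cand, function(s)
    min(S_equil$values - s * dark) >= -3e-4 - 1e-12, logical(1))
  expect_equal(d$s, cand[which(ok)[1]], tolerance = 1e-12)
})

test_that("degenerate decomposition inputs raise errors", {
  wl <- seq(450, 800, by = 2)
  dark <- gaussian_spectrum(gaussian_band(649, 50, 0.5), wl)$values
  S_dark <- spectrum(wl, dark)
  # equilibrium stronger than dark at the marker: inconsistent mixture
  expect_error(determine_subtraction_factor(spectrum(wl, 1.2 * dark),
                                            S_dark, 649, noise_floor = 0),
               "> 1")
  # dark state too weak at the marker
  expect_error(determine_subtraction_factor(spectrum(wl, 0.5 * dark),
                                            S_dark, 780, noise_floor = 1e-3),
               "too weak")
  expect_error(determine_subtraction_factor(spectrum(wl, dark), S_dark, 900,
                                            noise_floor = 0),
               "outside")
})

test_that("the pump-wavelength rescaling is the absorbed-photon ratio", {
  wl <- seq(320, 800, by = 1)
  dk <- spectrum(wl, 0.3 + 0 * wl)
  eq <- spectrum(wl, 0.3 + 0 * wl)
  expect_equal(as.numeric(scale_factor_for_pump(0.22, dk, eq, 385)), 0.22)
  eq2 <- spectrum(wl, (0.3 / 1.10) + 0 * wl)
  expect_equal(as.numeric(scale_factor_for_pump(0.22, dk, eq2, 385)),
               0.242, tolerance = 1e-9)
  expect_equal(as.numeric(scale_factor_for_pump(0, dk, eq, 385)), 0)
  bad <- spectrum(wl, 0 * wl)
  expect_error(scale_factor_for_pump(0.22, dk, bad, 385), "not positive")
})

test_that("pump-probe dataset subtraction recovers the pure photoproduct", {
  sc <- small_ta_scenario(noise_sigma = 0)
  pure <- simulate_ta(sc)
  sc_dark <- small_ta_scenario(noise_sigma = 0, tau1 = 100, tau2 = 900)
  dark <- simulate_ta(sc_dark)
  s_ta <- 0.24
  mixed <- pure
  mixed$values <- pure$values + s_ta * dark$values
  rec <- subtract_ta_datasets(mixed, dark, s_ta)
  expect_equal(rec$values, pure$values, tolerance = 1e-12)
  # s_ta = 0 leaves the data unchanged
  expect_equal(subtract_ta_datasets(mixed, dark, 0)$values, mixed$values)
  # mismatched grids refuse
  shifted <- dark
  shifted$wavelengths <- shifted$wavelengths + 1
  expect_error(subtract_ta_datasets(mixed, shifted, s_ta), "re-bin")
})
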