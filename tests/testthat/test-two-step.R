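test_that("degenerate rate limits behave as the scheme dictates", {
  times <- seq(0, 100, by = 1)
  # k1 = 0: no flux, everything constant
  p0 <- simulate_two_step(two_step_model(0, 0.5, 4.6, 2.4), times)
  expect_true(all(p0$free_bilin == 2.4) || max(abs(p0$free_bilin - 2.4)) < 1e-10)
  expect_true(max(p0$covalent) < 1e-10)

  # k2 = 0 with protein excess: everything ends non-covalent
  p1 <- simulate_two_step(two_step_model(1e6, 0, 4.6, 2.4),
                          c(0, 10, 100, 1000))
  expect_lt(p1$free_bilin[4], 1e-6)
  expect_equal(p1$noncovalent[4], 2.4, tolerance = 1e-6)
  expect_equal(max(p1$covalent), 0, tolerance = 1e-12)
})

test_that("fast uptake reduces to first-order attachment kinetics", {
  # k1 * A0 = 1e4 * k2: covalent formation approximates B0 * (1 - exp(-k2 t))
  k2 <- 1 / 18
  A0 <- 4.6
  k1 <- 1e4 * k2 / (A0 * 1e-6)
  times <- seq(0, 120, by = 0.5)
  p <- simulate_two_step(two_step_model(k1, k2, A0, 2.4), times)
  closed <- 2.4 * (1 - exp(-k2 * times))
  # absolute agreement everywhere (relative to total chromophore), and
  # pointwise relative agreement once conversion exceeds 25%
  expect_lt(max(abs(p$covalent - closed)) / 2.4, 1e-3)
  sel <- closed >= 0.25 * 2.4
  expect_lt(max(abs(p$covalent[sel] - closed[sel]) / closed[sel]), 1e-3)
})

test_that("mass is conserved on both ledgers for random rate constants", {
  set.seed(11)
  for (i in 1:8) {
    model <- two_step_model(10^runif(1, 3, 6.5), 10^runif(1, -3, 0),
                            runif(1, 1, 10), runif(1, 0.5, 5))
    p <- simulate_two_step(model, sort(c(0, 10^runif(12, -2, 3))))
    bilin <- p$free_bilin + p$noncovalent + p$covalent
    protein <- p$apo + p$noncovalent + p$covalent
    expect_lt(max(abs(bilin - model$B0)) / model$B0, 1e-8)
    expect_lt(max(abs(protein - model$A0)) / model$A0, 1e-8)
    # monotonicity: product non-decreasing, free bilin non-increasing
    expect_true(all(diff(p$covalent) >= -1e-10))
    expect_true(all(diff(p$free_bilin) <= 1e-10))
  }
})

test_that("pseudo-first-order uptake rate is k1*A0 under protein excess", {
  k1 <- 2e4
  A0 <- 50  # >> B0: pseudo-first-order regime
  p <- simulate_two_step(two_step_model(k1, 0, A0, 0.5),
                         seq(0, 5000, by = 5))
  # fit the non-covalent rise with a single exponential
  fit <- stats::nls(y ~ 0.5 * (1 - exp(-k * t)),
                    data = data.frame(t = p$times, y = p$noncovalent),
                    start = list(k = 1e-3))
  expect_equal(unname(coef(fit)["k"]), k1 * A0 * 1e-6, tolerance = 0.02)
})

test_that("spectra_from_profiles is the Beer-Lambert superposition", {
  species <- list(
    species_spectrum("free_bilin", gaussian_band(605, 60, 37.9)),
    species_spectrum("noncovalent", gaussian_band(690, 60, 70)),
    species_spectrum("covalent", gaussian_band(649, 60, 85)))
  zero <- structure(list(times = c(0, 1), apo = c(0, 0),
                         free_bilin = c(0, 0), noncovalent = c(0, 0),
                         covalent = c(0, 0)),
                    class = "concentration_profiles")
  wl <- seq(500, 780, by = 1)
  expect_true(all(spectra_from_profiles(zero, species, wl)$values == 0))

  # single nonzero species: rank 1 (outer product)
  one <- zero
  one$covalent <- c(1, 2.4)
  m <- spectra_from_profiles(one, species, wl)
  expect_equal(m$values[2, ], 2.4 * m$values[1, ], tolerance = 1e-12)
  # scale check: 2.4 uM of covalent at its 649 nm peak, 1 cm path
  expect_equal(max(m$values[2, ]), 85 * 2.4e-3, tolerance = 1e-6)

  expect_error(spectra_from_profiles(one, species[1:2], wl), "missing species")
})

test_that("the default PCB end state peaks at the covalent Q band", {
  sc <- small_pcb_scenario(noise_sigma = 0)
  p <- simulate_kinetics(sc$kinetics, c(0, 600))
  m <- spectra_from_profiles(p, sc$species, seq(500, 780, by = 0.5))
  final <- m$values[2, ]
  expect_equal(m$wavelengths[which.max(final)], 649, tolerance = 0.5)
  # full conversion: protein in excess, all 2.40 uM bilin covalent
  cov_only <- gaussian_spectrum(sc$species$covalent, m$wavelengths)$values
  expect_equal(final, 2.4e-3 * cov_only, tolerance = 1e-4)
})

test_that("fit_two_step recovers rate constants from noiseless data", {
  truth <- two_step_model(5e4, 0.05, 4.6, 2.4)
  sc <- small_pcb_scenario(noise_sigma = 0, kinetics = truth)
  sc$time_grid <- seq(1, 150, by = 3)
  m <- simulate_assembly(sc)
  fit <- fit_two_step(m, two_step_model(2e4, 0.02, 4.6, 2.4))
  # uptake is slow enough to be visible after the dead time: both recovered
  expect_equal(unname(coef(fit)["k1"]), 5e4, tolerance = 0.01)
  expect_equal(unname(coef(fit)["k2"]), 0.05, tolerance = 0.01)
})

test_that("attachment-limited data: fitted k2 matches single-exponential 1/tau", {
  truth <- two_step_model(1e6, 1 / 18, 4.6, 2.4)
  sc <- small_pcb_scenario(noise_sigma = 0, kinetics = truth)
  sc$time_grid <- seq(1, 150, by = 3)
  m <- simulate_assembly(sc)
  fit <- fit_two_step(m, two_step_model(3e5, 0.02, 4.6, 2.4))
  gfit <- global_exp_fit(m, n_exp = 1, with_offset = TRUE)
  expect_equal(unname(coef(fit)["k2"]), 1 / gfit$taus[1], tolerance = 0.02)
  # uptake finishes within the dead time: only a lower bound on k1
  expect_true("k1_lower_bound_only" %in% fit$identifiability)
})

test_that("uptake-limited data defeat the exponential fit but not the ODE fit", {
  truth <- two_step_model(5e3, 0.5, 4.6, 2.4) # second-order step limits
  sc <- small_pcb_scenario(noise_sigma = 0, kinetics = truth)
  sc$time_grid <- round(exp(seq(log(1), log(1500), length.out = 60)), 3)
  m <- simulate_assembly(sc)
  gfit <- global_exp_fit(m, n_exp = 1, with_offset = TRUE)
  ofit <- fit_two_step(m, two_step_model(2e3, 0.2, 4.6, 2.4))
  # the exponential fit deviates systematically; the mechanistic fit does not
  expect_gt(gfit$residual_rms, 20 * ofit$residual_rms)
  late <- m$times > 500
  exp_late_resid <- sqrt(mean(residuals(gfit)[late, ]^2))
  expect_gt(exp_late_resid, 1e-4) # visible late-time deviation in OD
})
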