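# Small, fast scenarios for unit tests (coarse grids; the full-size default
# scenarios are exercised in the acceptance tests).

small_pcb_scenario <- function(seed = 1, noise_sigma = 0,
                               kinetics = two_step_model(1e6, 1 / 18,
                                                         4.6, 2.40)) {
  assembly_scenario(
    species = list(
      species_spectrum("free_bilin", list(gaussian_band(605, 60, 37.9))),
      species_spectrum("noncovalent", list(gaussian_band(690, 60, 70))),
      species_spectrum("covalent", list(gaussian_band(649, 60, 85)))),
    kinetics = kinetics,
    time_grid = seq(1, 150, by = 1),
    wavelength_grid = seq(500, 780, by = 5),
    dead_time = 1, noise_sigma = noise_sigma, seed = seed)
}

small_ta_scenario <- function(seed = 1, noise_sigma = 0, phi_true = 0.06,
                              pa_amp = 0.9, esa_amp = 5, se_amp = -2,
                              tau1 = 200, tau2 = 1500, n_t = 40) {
  ta_scenario(
    gsb = gaussian_band(650, 45, -10),
    esa = if (esa_amp != 0) list(gaussian_band(520, 90, esa_amp)) else list(),
    se = if (se_amp != 0) list(gaussian_band(680, 50, se_amp)) else list(),
    pa = if (pa_amp != 0) list(gaussian_band(687, 45, pa_amp)) else list(),
    tau1 = tau1, tau2 = tau2, amp_split = 0.7, phi_true = phi_true,
    time_grid = exp(seq(log(10), log(20000), length.out = n_t)),
    wavelength_grid = seq(500, 780, by = 4),
    noise_sigma = noise_sigma, seed = seed)
}

# independent dense-grid variable-projection oracle: profiled RSS computed
# with lm.fit (not the package's qr path)
oracle_rss <- function(taus, times, Y, with_offset = TRUE) {
  X <- exp(-outer(times, 1 / taus))
  if (with_offset) X <- cbind(X, 1)
  fit <- stats::lm.fit(X, Y)
  sum(fit$residuals^2)
}
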