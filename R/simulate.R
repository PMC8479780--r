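#' Simulate a chromophore-assembly time series
#'
#' Runs the scenario's kinetic model from t = 0 (mixing), maps the
#' concentration profiles onto absorbance via the Beer-Lambert
#' superposition of the three species spectra (1 cm pathlength), discards
#' times before the mixing dead time and adds seeded homoscedastic Gaussian
#' noise.
#'
#' @param scenario An [assembly_scenario()].
#' @return A [trmatrix()] in OD with ground truth in `metadata`.
#' @export
simulate_assembly <- function(scenario) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  times <- scenario$time_grid[scenario$time_grid >= scenario$dead_time]
  profiles <- tryCatch(
    simulate_kinetics(scenario$kinetics, times),
    error = function(e) stop(
      "simulate_assembly: kinetics failed for scenario (seed ",
      scenario$seed, "): ", conditionMessage(e), call. = FALSE))
  m <- spectra_from_profiles(profiles, scenario$species,
                             scenario$wavelength_grid, pathlength = 1)
  set.seed(scenario$seed)
  if (scenario$noise_sigma > 0)
    m$values <- m$values + matrix(
      stats::rnorm(length(m$values), 0, scenario$noise_sigma),
      nrow = nrow(m$values))
  m$metadata <- list(scenario = "assembly", seed = scenario$seed,
                     dead_time = scenario$dead_time,
                     noise_sigma = scenario$noise_sigma,
                     kinetics = unclass(scenario$kinetics),
                     kinetics_class = class(scenario$kinetics))
  m
}

#' Simulate a pump-probe (transient absorption) matrix
#'
#' Builds
#' \deqn{\Delta A(t,\lambda) = D_1(\lambda) e^{-t/\tau_1} +
#'   D_2(\lambda) e^{-t/\tau_2} + \Delta A_\infty(\lambda) + \epsilon}
#' where the non-decaying Lumi spectrum is
#' `dA_inf = phi_true * gsb + pa` and the decaying spectra partition
#' `gsb + esa + se - dA_inf` with fractions `amp_split` and
#' `1 - amp_split`. No instrument-response convolution is applied: the
#' earliest probe delay (10 ps) lies well past the pump pulse.
#'
#' @param scenario A [ta_scenario()].
#' @return A [trmatrix()] in mOD/ps with ground truth in `metadata`.
#' @export
simulate_ta <- function(scenario) {
  stopifnot(inherits(scenario, "ta_scenario"))
  tg <- scenario$time_grid
  if (min(tg) < 10 || max(tg) > 20000)
    warning("simulate_ta: time grid extends outside 10 ps - 20 ns; ",
            "values kept")
  wl <- scenario$wavelength_grid
  comp <- function(b) if (length(b)) gaussian_spectrum(b, wl)$values
                      else numeric(length(wl))
  gsb <- comp(scenario$gsb); esa <- comp(scenario$esa)
  se <- comp(scenario$se); pa <- comp(scenario$pa)
  d_inf <- scenario$phi_true * gsb + pa
  decaying <- gsb + esa + se - d_inf
  d1 <- scenario$amp_split * decaying
  d2 <- (1 - scenario$amp_split) * decaying
  vals <- exp(-tg / scenario$tau1) %o% d1 +
    exp(-tg / scenario$tau2) %o% d2 +
    rep(1, length(tg)) %o% d_inf
  set.seed(scenario$seed)
  if (scenario$noise_sigma > 0)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, scenario$noise_sigma),
                          nrow = nrow(vals))
  trmatrix(tg, wl, vals, time_unit = "ps", value_unit = "mOD",
           metadata = list(scenario = "ta", state = scenario$state,
                           seed = scenario$seed,
                           tau1 = scenario$tau1, tau2 = scenario$tau2,
                           amp_split = scenario$amp_split,
                           phi_true = scenario$phi_true,
                           noise_sigma = scenario$noise_sigma))
}

#' Simulate a photostationary-equilibrium spectrum pair
#'
#' Returns the measured dark-state spectrum and the measured equilibrium
#' spectrum `S_equil = f * S_dark_pure + (1 - f) * g * S_phot_pure`, each
#' with independent seeded Gaussian noise. With the default rescaling
#' `g = 1` the ground-truth subtraction factor of the decomposition
#' `S_phot = S_equil - s * S_dark` equals the dark fraction `f`.
#'
#' @param scenario An [equilibrium_scenario()].
#' @param g Photoproduct rescaling factor (default 1).
#' @return A list with [spectrum()]s `S_dark` and `S_equil`, plus the
#'   ground truth `f` and `marker_wavelength`.
#' @export
simulate_equilibrium <- function(scenario, g = 1) {
  stopifnot(inherits(scenario, "equilibrium_scenario"))
  wl <- scenario$wavelength_grid
  dark_pure <- gaussian_spectrum(scenario$dark, wl)$values
  phot_pure <- gaussian_spectrum(scenario$photoproduct, wl)$values
  equil_pure <- scenario$f * dark_pure + (1 - scenario$f) * g * phot_pure
  set.seed(scenario$seed)
  n <- length(wl)
  noise <- if (scenario$noise_sigma > 0)
    matrix(stats::rnorm(2 * n, 0, scenario$noise_sigma), ncol = 2)
  else matrix(0, n, 2)
  list(S_dark = spectrum(wl, dark_pure + noise[, 1], label = "S_dark"),
       S_equil = spectrum(wl, equil_pure + noise[, 2], label = "S_equil"),
       f = scenario$f, marker_wavelength = scenario$marker_wavelength)
}
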