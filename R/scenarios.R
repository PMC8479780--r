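#' Exponential-phase surrogate kinetics
#'
#' Surrogate concentration model for assembly reactions whose observed
#' kinetics are well described by a sum of exponential phases rather than by
#' the mechanistic two-step scheme: a promptly formed non-covalent pool
#' (fraction `frac_noncov` of the chromophore) converts to the covalent
#' product with time constant `tau_noncov`, while the remaining free
#' chromophore is consumed (and immediately attached) with time constant
#' `tau_free`. Every absorbance channel is then a sum of two exponentials
#' plus a constant.
#'
#' @param tau_noncov Time constant (s) of the non-covalent pool's conversion.
#' @param tau_free Time constant (s) of the slow free-chromophore uptake.
#' @param frac_noncov Fraction of the chromophore in the prompt pool, in
#'   \[0, 1\].
#' @param A0,B0 Initial apo-protein and chromophore concentrations (uM).
#' @return An object of class `"exp_phase_model"`.
#' @export
exp_phase_model <- function(tau_noncov, tau_free, frac_noncov, A0, B0) {
  if (tau_noncov <= 0 || tau_free <= 0)
    stop("exp_phase_model: time constants must be > 0", call. = FALSE)
  if (frac_noncov < 0 || frac_noncov > 1)
    stop("exp_phase_model: frac_noncov must lie in [0, 1]", call. = FALSE)
  if (A0 <= 0 || B0 <= 0)
    stop("exp_phase_model: initial concentrations must be > 0", call. = FALSE)
  structure(list(tau_noncov = tau_noncov, tau_free = tau_free,
                 frac_noncov = frac_noncov, A0 = A0, B0 = B0),
            class = "exp_phase_model")
}

#' Concentration profiles for either kinetic model
#'
#' Dispatches to [simulate_two_step()] for a [two_step_model()] or evaluates
#' the closed-form phases of an [exp_phase_model()].
#'
#' @param model A `"two_step_model"` or `"exp_phase_model"`.
#' @param times Increasing times (s).
#' @return A `"concentration_profiles"` object.
#' @export
simulate_kinetics <- function(model, times) {
  if (inherits(model, "two_step_model")) return(simulate_two_step(model, times))
  if (!inherits(model, "exp_phase_model"))
    stop("simulate_kinetics: unsupported kinetic model class", call. = FALSE)
  times <- as.numeric(times)
  noncov <- model$B0 * model$frac_noncov * exp(-times / model$tau_noncov)
  free <- model$B0 * (1 - model$frac_noncov) * exp(-times / model$tau_free)
  cov <- model$B0 - noncov - free
  structure(list(times = times, apo = model$A0 - noncov - cov,
                 free_bilin = free, noncovalent = noncov, covalent = cov),
            class = "concentration_profiles")
}

.validate_grid <- function(x, what) {
  if (length(x) < 2L || any(diff(x) <= 0))
    stop(what, " must be strictly increasing with >= 2 points", call. = FALSE)
  as.numeric(x)
}

#' Assembly scenario: ground truth for a synthetic assembly experiment
#'
#' Bundles the three species spectra, a kinetic model, acquisition grids,
#' dead time, noise level and seed.
#'
#' @param species Named list of three [species_spectrum()]s: `free_bilin`,
#'   `noncovalent`, `covalent`.
#' @param kinetics A [two_step_model()] or [exp_phase_model()].
#' @param time_grid Recording times (s), strictly increasing, all
#'   `>= dead_time`.
#' @param wavelength_grid Wavelength grid (nm), strictly increasing.
#' @param dead_time Mixing dead time (s); the reaction starts at t = 0 but
#'   no spectra exist before `dead_time` (default 1 s).
#' @param noise_sigma Additive Gaussian noise sd (OD), default 1 mOD.
#' @param seed Integer random seed (mandatory).
#' @return An object of class `"assembly_scenario"`.
#' @export
assembly_scenario <- function(species, kinetics, time_grid, wavelength_grid,
                              dead_time = 1, noise_sigma = 1e-3, seed) {
  names(species) <- vapply(species, function(s) s$name, character(1))
  missing <- setdiff(c("free_bilin", "noncovalent", "covalent"),
                     names(species))
  if (length(missing))
    stop("assembly_scenario: missing species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  time_grid <- .validate_grid(time_grid, "time_grid")
  if (any(time_grid < dead_time))
    stop("assembly_scenario: all recording times must be >= dead_time",
         call. = FALSE)
  if (noise_sigma < 0)
    stop("assembly_scenario: noise_sigma must be >= 0", call. = FALSE)
  if (missing(seed)) stop("assembly_scenario: seed is mandatory", call. = FALSE)
  structure(list(species = species, kinetics = kinetics,
                 time_grid = time_grid,
                 wavelength_grid = .validate_grid(wavelength_grid,
                                                  "wavelength_grid"),
                 dead_time = dead_time, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "assembly_scenario")
}

#' Pump-probe (transient absorption) scenario
#'
#' Ground truth for a synthetic pump-probe matrix: signed Gaussian-band
#' composites for ground-state bleach (GSB, <= 0), excited-state absorption
#' (ESA, >= 0), stimulated emission (SE, <= 0) and photoproduct absorption
#' (PA, >= 0); two excited-state decay constants; the amplitude split
#' between them; and the true photochemical quantum yield. The non-decaying
#' (Lumi) spectrum is `phi_true * gsb + pa` and the decaying amplitude
#' `gsb + esa + se - Lumi` is partitioned by `amp_split`.
#'
#' @param gsb,esa,se,pa Lists of [gaussian_band()]s (mOD scale). GSB and SE
#'   bands must have amplitudes <= 0, ESA and PA >= 0. `esa`, `se`, `pa` may
#'   be empty lists.
#' @param tau1,tau2 Excited-state decay constants (ps), `tau1 < tau2`.
#' @param amp_split Fraction of the decaying amplitude on `tau1`, in \[0, 1\].
#' @param phi_true Ground-truth quantum yield in \[0, 1\].
#' @param time_grid Probe delays (ps), log-spaced within 10 ps - 20 ns.
#' @param wavelength_grid Probe wavelengths (nm).
#' @param noise_sigma Additive Gaussian noise sd (mOD), default 0.1.
#' @param seed Integer random seed (mandatory).
#' @param state Optional state label (`"Pr"`, `"Pg"`, `"Pfr"`, `"Po"`).
#' @return An object of class `"ta_scenario"`.
#' @export
ta_scenario <- function(gsb, esa = list(), se = list(), pa = list(),
                        tau1, tau2, amp_split = 0.5, phi_true,
                        time_grid, wavelength_grid, noise_sigma = 0.1,
                        seed, state = "") {
  as_bands <- function(b) if (inherits(b, "gaussian_band")) list(b) else b
  gsb <- as_bands(gsb); esa <- as_bands(esa)
  se <- as_bands(se); pa <- as_bands(pa)
  amp <- function(b) vapply(b, function(x) x$amplitude, numeric(1))
  if (length(gsb) == 0L || any(amp(gsb) > 0))
    stop("ta_scenario: gsb must be non-empty with amplitudes <= 0",
         call. = FALSE)
  if (any(amp(se) > 0))
    stop("ta_scenario: se amplitudes must be <= 0", call. = FALSE)
  if (any(amp(esa) < 0) || any(amp(pa) < 0))
    stop("ta_scenario: esa and pa amplitudes must be >= 0", call. = FALSE)
  if (tau1 >= tau2)
    stop("ta_scenario: tau1 must be < tau2", call. = FALSE)
  if (phi_true < 0 || phi_true > 1)
    stop("ta_scenario: phi_true must lie in [0, 1]", call. = FALSE)
  if (amp_split < 0 || amp_split > 1)
    stop("ta_scenario: amp_split must lie in [0, 1]", call. = FALSE)
  if (missing(seed)) stop("ta_scenario: seed is mandatory", call. = FALSE)
  structure(list(gsb = gsb, esa = esa, se = se, pa = pa,
                 tau1 = tau1, tau2 = tau2, amp_split = amp_split,
                 phi_true = phi_true,
                 time_grid = .validate_grid(time_grid, "time_grid"),
                 wavelength_grid = .validate_grid(wavelength_grid,
                                                  "wavelength_grid"),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 state = state),
            class = "ta_scenario")
}

#' Photostationary equilibrium scenario
#'
#' Ground truth for a photostationary mixture: the dark-state and
#' photoproduct spectra, the dark fraction `f` (the true subtraction
#' factor), and the marker wavelength where the photoproduct is (nearly)
#' transparent so the dark-state contribution can be nulled.
#'
#' @param dark,photoproduct [species_spectrum()]s (OD scale).
#' @param f Dark-state fraction in the equilibrium, in \[0, 1\].
#' @param marker_wavelength Marker band (nm), e.g. 649 (PCB) or 697 (BV).
#' @param wavelength_grid Wavelength grid (nm).
#' @param noise_sigma Additive Gaussian noise sd (OD), default 0.5 mOD.
#' @param seed Integer random seed (mandatory).
#' @return An object of class `"equilibrium_scenario"`.
#' @export
equilibrium_scenario <- function(dark, photoproduct, f, marker_wavelength,
                                 wavelength_grid, noise_sigma = 5e-4, seed) {
  if (f < 0 || f > 1)
    stop("equilibrium_scenario: f must lie in [0, 1]", call. = FALSE)
  if (missing(seed))
    stop("equilibrium_scenario: seed is mandatory", call. = FALSE)
  wavelength_grid <- .validate_grid(wavelength_grid, "wavelength_grid")
  phot_at_marker <- gaussian_spectrum(photoproduct, wavelength_grid)
  pm <- spectrum_at(phot_at_marker, marker_wavelength)
  if (pm > max(2 * noise_sigma, 2e-4))
    warning("equilibrium_scenario: photoproduct is not transparent at the ",
            "marker wavelength (", signif(pm, 3), " OD)")
  structure(list(dark = dark, photoproduct = photoproduct, f = f,
                 marker_wavelength = marker_wavelength,
                 wavelength_grid = wavelength_grid,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "equilibrium_scenario")
}

# --- default study scenarios ------------------------------------------------

#' Default synthetic scenarios
#'
#' Ready-made scenarios emulating the in vitro study conditions: 2 mL of
#' 3 uM chromophore mixed with 0.5 mL of 23 uM apo-protein (4.6 uM protein,
#' 2.40 uM chromophore after mixing), 1 cm pathlength, ~1 s mixing dead
#' time, spectra every 0.2 s (PCB) or 2 s (BV), 1 mOD measurement noise.
#'
#' `default_pcb_assembly_scenario()`: attachment-limited two-step kinetics
#' (fast uptake, k1 = 1e6 M^-1 s^-1; covalent attachment k2 = 1/18 s^-1);
#' free-bilin Soret 385 nm and Q 605 nm (peak extinction 37.9 mM^-1 cm^-1),
#' non-covalent intermediate Q 690 nm, covalent product Q 649 nm.
#'
#' `default_bv_assembly_scenario()`: uptake-limited surrogate kinetics (sum
#' of 14 s and 385 s phases); free biliverdin Q 690 nm (broad, peak
#' 30.8 mM^-1 cm^-1), intermediate Q 705 nm, covalent product Q 697 nm.
#'
#' `bv_two_step_scenario()`: mechanistic uptake-limited two-step variant of
#' the BV scenario (k2 >> k1*A0) for comparing exponential and ODE fits.
#'
#' @param seed Integer seed.
#' @param noise_sigma Noise sd (OD).
#' @return An `"assembly_scenario"`.
#' @name default_scenarios
NULL

.pcb_species <- function() list(
  species_spectrum("free_bilin", list(
    gaussian_band(385, 50, 55), gaussian_band(605, 60, 37.9))),
  species_spectrum("noncovalent", list(
    gaussian_band(385, 50, 45), gaussian_band(690, 60, 70))),
  species_spectrum("covalent", list(
    gaussian_band(385, 50, 35), gaussian_band(649, 60, 85))))

.bv_species <- function() list(
  species_spectrum("free_bilin", list(
    gaussian_band(380, 55, 40), gaussian_band(690, 160, 30.8))),
  species_spectrum("noncovalent", list(
    gaussian_band(385, 55, 45), gaussian_band(705, 32, 105))),
  species_spectrum("covalent", list(
    gaussian_band(390, 55, 40), gaussian_band(697, 38, 80))))

#' @rdname default_scenarios
#' @export
default_pcb_assembly_scenario <- function(seed = 101, noise_sigma = 1e-3) {
  assembly_scenario(
    species = .pcb_species(),
    kinetics = two_step_model(k1 = 1e6, k2 = 1 / 18, A0 = 4.6, B0 = 2.40),
    time_grid = seq(1, 150, by = 0.2),
    wavelength_grid = seq(450, 800, by = 0.5),
    dead_time = 1, noise_sigma = noise_sigma, seed = seed)
}

#' @rdname default_scenarios
#' @export
default_bv_assembly_scenario <- function(seed = 102, noise_sigma = 1e-3) {
  assembly_scenario(
    species = .bv_species(),
    kinetics = exp_phase_model(tau_noncov = 14, tau_free = 385,
                               frac_noncov = 0.5, A0 = 4.6, B0 = 2.40),
    time_grid = seq(1, 1500, by = 2),
    wavelength_grid = seq(450, 800, by = 0.5),
    dead_time = 1, noise_sigma = noise_sigma, seed = seed)
}

#' @rdname default_scenarios
#' @export
bv_two_step_scenario <- function(seed = 103, noise_sigma = 1e-3) {
  # uptake rate-limiting: k1*A0 = 0.023 s^-1 << k2
  assembly_scenario(
    species = .bv_species(),
    kinetics = two_step_model(k1 = 5e3, k2 = 0.5, A0 = 4.6, B0 = 2.40),
    time_grid = seq(1, 1500, by = 2),
    wavelength_grid = seq(450, 800, by = 0.5),
    dead_time = 1, noise_sigma = noise_sigma, seed = seed)
}

#' Default pump-probe scenarios for the four photochemical states
#'
#' One scenario per state (Pr, Pg, Pfr, Po analogs): ground-state bleach at
#' the state's Q band, broad blue-shifted excited-state absorption,
#' stimulated emission on the red flange, and a weak Lumi photoproduct
#' absorption band near the bleach. Ground-truth quantum yield 0.06 for all
#' states; biexponential excited-state decay with the far-red (BV) states
#' decaying several-fold faster than the PCB states. Probe delays: 60
#' log-spaced points, 10 ps - 20 ns; noise 0.1 mOD.
#'
#' @param state One of `"Pr"`, `"Pg"`, `"Pfr"`, `"Po"`.
#' @param seed Integer seed (default: a fixed per-state value).
#' @param phi_true Ground-truth quantum yield (default 0.06).
#' @param noise_sigma Noise sd (mOD).
#' @param overlap_scale Scale factor applied to the ESA, SE and PA band
#'   amplitudes (0 removes all overlapping components, leaving a pure
#'   bleach; used for estimator-consistency studies).
#' @return A `"ta_scenario"`.
#' @export
default_ta_scenario <- function(state = c("Pr", "Pg", "Pfr", "Po"),
                                seed = NULL, phi_true = 0.06,
                                noise_sigma = 0.1, overlap_scale = 1) {
  state <- match.arg(state)
  p <- switch(state,
    Pr = list(gsb = c(650, 45, -10), esa = c(520, 90, 5),
              se = c(680, 50, -2), pa = c(687, 45, 0.9),
              tau1 = 200, tau2 = 1500, seed = 201),
    Pg = list(gsb = c(565, 50, -8), esa = c(470, 90, 4),
              se = c(610, 55, -1.5), pa = c(580, 35, 0.4),
              tau1 = 150, tau2 = 1000, seed = 202),
    Pfr = list(gsb = c(697, 45, -10), esa = c(560, 100, 4),
               se = c(730, 55, -1.8), pa = c(722, 45, 0.65),
               tau1 = 45, tau2 = 330, seed = 203),
    Po = list(gsb = c(610, 48, -9), esa = c(500, 90, 4),
              se = c(650, 55, -1.5), pa = c(585, 40, 0.45),
              tau1 = 60, tau2 = 400, seed = 204))
  band <- function(v, scale = 1)
    list(gaussian_band(v[1], v[2], v[3] * scale))
  ta_scenario(
    gsb = band(p$gsb),
    esa = band(p$esa, overlap_scale), se = band(p$se, overlap_scale),
    pa = band(p$pa, overlap_scale),
    tau1 = p$tau1, tau2 = p$tau2, amp_split = 0.7, phi_true = phi_true,
    time_grid = exp(seq(log(10), log(20000), length.out = 60)),
    wavelength_grid = seq(450, 780, by = 2),
    noise_sigma = noise_sigma,
    seed = if (is.null(seed)) p$seed else seed,
    state = state)
}

#' Default photostationary equilibrium scenarios
#'
#' PCB variant: red-absorbing dark state (Q 649 nm) mixed with the
#' green-absorbing photoproduct (Q 545 nm, transparent at the 649 nm
#' marker), dark fraction 0.22. BV variant: far-red dark state (Q 697 nm)
#' with the orange-absorbing photoproduct (Q 600 nm, transparent at
#' 697 nm), dark fraction 0.35. Grids cover 320-800 nm so the 385 nm pump
#' wavelength is available for pump-fraction scaling.
#'
#' @param chromophore `"pcb"` or `"bv"`.
#' @param f Dark fraction (default: the variant's standard value).
#' @param seed Integer seed.
#' @param noise_sigma Noise sd (OD).
#' @return An `"equilibrium_scenario"`.
#' @export
default_equilibrium_scenario <- function(chromophore = c("pcb", "bv"),
                                         f = NULL, seed = NULL,
                                         noise_sigma = 5e-4) {
  chromophore <- match.arg(chromophore)
  if (chromophore == "pcb") {
    dark <- species_spectrum("dark_state", list(
      gaussian_band(385, 55, 0.35), gaussian_band(600, 60, 0.15),
      gaussian_band(649, 50, 0.50)))
    phot <- species_spectrum("photoproduct", list(
      gaussian_band(370, 55, 0.30), gaussian_band(545, 55, 0.40)))
    if (is.null(f)) f <- 0.22
    marker <- 649
    if (is.null(seed)) seed <- 301
  } else {
    dark <- species_spectrum("dark_state", list(
      gaussian_band(390, 55, 0.30), gaussian_band(640, 60, 0.12),
      gaussian_band(697, 50, 0.50)))
    phot <- species_spectrum("photoproduct", list(
      gaussian_band(375, 55, 0.28), gaussian_band(600, 55, 0.42)))
    if (is.null(f)) f <- 0.35
    marker <- 697
    if (is.null(seed)) seed <- 302
  }
  equilibrium_scenario(dark, phot, f = f, marker_wavelength = marker,
                       wavelength_grid = seq(320, 800, by = 2),
                       noise_sigma = noise_sigma, seed = seed)
}
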