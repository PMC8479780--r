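# photokin

Spectro-kinetic analysis of bilin photoreceptor assembly and primary
photochemistry, in R.

Cyanobacteriochromes (CBCRs) and related phytochromes sense light through a
bilin chromophore — phycocyanobilin (PCB) or biliverdin (BV) — bound
covalently to a conserved cysteine in a GAF domain. Two measurements
characterise such a photoreceptor *in vitro*: seconds-scale absorption
spectra recorded while the apo-protein assembles with the free bilin, and
picosecond pump–probe difference spectra of the assembled holo-protein's
photochemistry. `photokin` provides the full analysis chain for both, plus
a seeded synthetic-data generator with known ground truth so that every
stage is testable without laboratory data.

## What it computes

- **Two-step assembly kinetics** — the scheme
  `apo + bilin --k1--> noncovalent --k2--> covalent` as mass-action ODEs
  (`simulate_two_step()`), Beer–Lambert mapping onto spectra, a mechanistic
  fit with species spectra profiled out by non-negative least squares
  (`fit_two_step()`), difference-spectrum and Q-band peak-tracking
  diagnostics for the red-shifted non-covalent intermediate.
- **Global multiexponential fitting** (`global_exp_fit()`) — variable
  projection: amplitudes (decay-associated spectra
  `D_i(lambda)` and a non-decaying component `D_inf(lambda)`) are solved
  exactly by linear least squares for each trial of the time constants

  `A(t, lambda) = sum_i D_i(lambda) exp(-t/tau_i) + D_inf(lambda)`,

  with a multi-started bounded search over `tau`. Returns a classed model
  object with `coef`, `predict`, `fitted`, `residuals`, `summary` and
  `plot` methods.
- **Photostationary decomposition**
  (`determine_subtraction_factor()`) — extracts the pure photoproduct
  spectrum via `S_phot = S_equil - s * S_dark`, determining `s` by marker-
  band nulling (649 nm PCB / 697 nm BV) under over-subtraction constraints,
  and rescales `s` to the pump wavelength for pump–probe dataset
  subtraction (`scale_factor_for_pump()`, `subtract_ta_datasets()`).
- **Quantum yields from the ground-state bleach**
  (`fit_ta()`, `estimate_qy()`) — two exponentials plus a non-decaying
  Lumi spectrum; `Phi_L` as the GSB ratio at the Lumi bleach minimum,
  with a bleach-shift diagnostic flagging overlap-induced underestimation
  (`gsb_shift_diagnostic()`).
- **Synthetic scenarios** emulating the study conditions (4.6 uM protein /
  2.40 uM bilin after mixing, 1 s dead time, 1 mOD noise, 10 ps–20 ns
  pump–probe window), plus a one-call pipeline (`run_pipeline()`).

## Worked example

```r
library(photokin)

# assembly of the PCB adduct: simulate, bin like the experiment, fit
sc  <- default_pcb_assembly_scenario(seed = 1)
m   <- simulate_assembly(sc)                      # 746 x 701 matrix, OD
mb  <- bin_time_log(bin_wavelength(m, 7), 10)     # 7-pixel + log-time bins
fit <- global_exp_fit(mb, n_exp = 1, with_offset = TRUE)
fit
#> <global_fit> 1 exponential(s) + offset, 22 x 101 data
#>   tau1 = 18.3183 +/- 0.032 s
#>   residual rms: 0.0006278 OD
```

The fitted 18.3 s constant is the covalent-attachment step (`1/k2`,
ground truth 18 s): with PCB the uptake finishes inside the mixing dead
time and a single exponential describes the data.

```r
# photostationary mixture: recover the dark-state subtraction factor
eq  <- simulate_equilibrium(default_equilibrium_scenario("pcb", seed = 1))
dec <- determine_subtraction_factor(eq$S_equil, eq$S_dark,
                                    marker = 649, noise_floor = 1e-3)
dec
#> <decomposition> s = 0.2198 (marker 648.0 nm, residual 0, min -0.00125)

# pump-probe: excited-state decay and quantum yield of the Pfr analog
ta <- fit_ta(simulate_ta(default_ta_scenario("Pfr", seed = 1)))
ta
#> State: Pfr
#> <global_fit> 2 exponential(s) + offset, 60 x 166 data
#>   tau1 = 44.2032 +/- 0.41 ps
#>   tau2 = 320.845 +/- 4.7 ps
#>   residual rms: 0.09876 mOD
estimate_qy(ta, t0 = 10)
#> <qy_estimate> Phi = 0.05588 (Lumi GSB minimum 685.8 nm, t0 = 10 ps)
```

The recovered subtraction factor (0.22 ground truth) is the residual
dark-state fraction in the photostationary mixture; the quantum yield
(0.06 ground truth) is the fraction of the initial ground-state bleach
surviving in the non-decaying Lumi spectrum — a lower bound wherever
photoproduct absorption overlaps the bleach, which the
`gsb_shift_diagnostic()` flag reports.

See `vignettes/photokin-methods.Rmd` for the models, assumptions, default
parameters and numerical choices.

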