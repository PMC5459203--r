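# mofkinetics

Quantitative analysis of guest-molecule loading and release by porous
metal-organic framework (MOF) nanoparticles, for experimentalists
characterizing nanocarriers by depletion isotherms and time-resolved
fluorescence quenching.

MOF nanoparticles such as MIL-100(Fe) and MIL-101(Cr) adsorb drug-sized
guests (here: fluorescein disodium, M = 412.3 g/mol) in very large
amounts — thousands to tens of thousands of molecules per particle —
because uptake is governed by their internal surface, not their volume.
The package implements the complete analysis chain:

* **Particle ensemble** — per-particle mass m = (4/3)πr³ρ from the TEM
  radius and crystallographic density, particles per mg, molar particle
  concentration, and kernel-density size summaries (mean, CV, FWHM).
* **Sorption equilibrium** — Langmuir fits P(c) = P·c/(c + K_D) to
  depletion isotherms (bounded Levenberg–Marquardt, proportional
  weighting), absorbance calibration A = m·c + t, and payload accounting:
  molecules per particle, weight-payload ratio, and the area occupied per
  guest molecule against a BET surface area.
* **Kinetics** — baseline normalization of fluorescence-quench traces,
  first-order fits F(t) = F∞ + A·e^(−kt) with an explicit "no detectable
  loading" outcome, the diffusion-limited capture model
  τ(c_NP) = A·c_NP⁻¹ + τ₀ (with τ_diff ≈ πr²ρ/(18·c_NP·D_ex) as the
  closed-form external-diffusion estimate), and the intraparticle
  diffusion constant D_intra ≈ r²/τ₀.
* **Reaction–diffusion simulator** — a mechanistic forward model of the
  diffusion–immobilization picture (Smoluchowski capture from a well-mixed
  bath, hindered radial pore diffusion over concentric shells,
  Langmuir-type adsorption/desorption per shell) with a mass-conservation
  ledger, used for validation against closed-form oracles.
* **Synthetic data** — seeded, pure generators for isotherms, traces and
  lognormal TEM size samples, plus `make_fixtures()`/`run_pipeline()` for
  an end-to-end, config-driven analysis with JSON reports.

## Worked example

```r
library(mofkinetics)

mil100 <- particle_species("MIL-100(Fe)", radius_nm = 26.5,
                           density_g_cm3 = 0.98, s_bet_m2_g = 2004)
mil100
#> <mof_species> MIL-100(Fe)
#>   r = 26.5 nm, rho = 0.98 g/cm^3
#>   mass/NP = 7.64e-17 g, 1.31e+13 NPs/mg (21.7 pmol/mg)
#>   S_BET = 2004 m^2/g
```

One 26.5 nm particle weighs 7.6 × 10⁻¹⁷ g, so a milligram of carrier is
1.31 × 10¹³ particles (21.7 pmol). Fit a depletion isotherm (here a
synthetic one generated at the bench design with 2% triplicate noise) and
derive the payload figures:

```r
design <- c(5, 10, 20, 50, 100, 200, 400, 700, 1000, 1500)  # ug/mL
iso <- gen_isotherm(p_max = 649.4, k_d = 4.4, design,
                    noise = noise_model(0.02, 0, seed = 1), replicates = 3)
fit <- fit_langmuir(iso, m_guest = 412.3)
fit
#> <mof_langmuir_fit> P_max = 650.9 ug/mg (1.58 umol/mg), K_D = 4.34 ug/mL (10.5 uM)
payload_summary(fit, mil100)
#> <mof_payload_summary> MIL-100(Fe): 7.26e+04 molecules/NP, weight ratio 65%, 2.1 nm^2 per molecule
```

A K_D of ~4.4 µg/mL (≈11 µM) with saturation at ~650 µg per mg of carrier
means a 65% weight-payload ratio; spread over the 2004 m²/g internal BET
area, each guest occupies ~2 nm² — a densely packed internal monolayer.

Loading kinetics from a fluorescence-quench trace, and the separation of
external diffusion from internal transport:

```r
tr <- normalize_trace(gen_trace(rate = 13e-3, offset = 0.2, baseline_s = 60,
                                duration_s = 500,
                                noise = noise_model(0.01, 0, seed = 3)))
fit_exponential(tr)
#> <mof_decay_fit> rate = 0.013 1/s (se 2.4e-05), tau = 76.68 s, offset = 0.2, R^2 = 0.9997

cs <- c(0.001, 0.002, 0.004, 0.01, 0.02)      # particle conc., mg/cm^3
taus <- sapply(seq_along(cs), function(i)
  fit_exponential(normalize_trace(gen_trace(
    1 / (0.3 / cs[i] + 60), 0.15, 60, max(500, 4 * (0.3 / cs[i] + 60)),
    noise_model(0.01, 0, 10 + i))))$tau)
cap <- fit_capture_model(cs, taus)
cap
#> <mof_capture_fit> tau = A/c_NP + tau0: A = 0.3 s*mg/cm^3, tau0 = 60 s
d_intra_estimate(25, cap$tau0)
#> [1] 1.04e-17
```

The loading time falls as 1/c_NP (external diffusion to the particles) but
levels off at τ₀ ≈ 60 s — internal transport and sorption — which for a
~25 nm particle radius corresponds to an effective intraparticle diffusion
constant of ~10⁻¹⁷ m²/s, roughly 10⁷-fold below the bulk diffusivity of
fluorescein in water (3.9 × 10⁻¹⁰ m²/s).

The methods vignette (`vignettes/mof-guest-kinetics.Rmd`) documents the
model assumptions, the simulator's default parameters, and the numerical
choices in detail.

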