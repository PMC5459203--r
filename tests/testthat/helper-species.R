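# Reference carrier definitions used across the suite: the two mesoporous
# MOF structure types, with TEM mean radii, crystallographic densities and
# BET surface areas.

mil100 <- function() particle_species("MIL-100(Fe)", radius_nm = 26.5,
                                      density_g_cm3 = 0.98,
                                      s_bet_m2_g = 2004)

mil101 <- function() particle_species("MIL-101(Cr)", radius_nm = 9.45,
                                      density_g_cm3 = 0.62,
                                      s_bet_m2_g = 3205)

M_FLUORESCEIN <- 412.3  # g/mol, fluorescein disodium

# equilibrium free concentration of the well-mixed-bath + Langmuir-sites
# system, by conservation-of-mass fixed point (independent of the ODE path)
equilibrium_oracle <- function(scenario) {
  sp <- scenario$species
  vp <- (4 / 3) * pi * (sp$radius_nm * 1e-9)^3
  np <- scenario$c_np * scenario$bath_volume * sp$np_per_mg
  vb <- scenario$bath_volume * 1e-6
  smax <- scenario$site_capacity / (mof_constants$N_A * vp)
  kd <- scenario$k_d_uM * 1e-3                       # uM -> mol/m^3
  total <- scenario$guest_conc * 1e-3 * vb           # mol
  f <- function(c) c * vb + np * vp * (c + smax * c / (c + kd)) - total
  ceq <- stats::uniroot(f, c(1e-300, scenario$guest_conc * 1e-3),
                        tol = 1e-25)$root
  list(free_uM = ceq * 1e3,
       adsorbed_per_np = vp * smax * ceq / (ceq + kd) * mof_constants$N_A)
}
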