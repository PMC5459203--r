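# The simulator couples a well-mixed bath to identical porous spheres:
# Smoluchowski capture at the surface, hindered radial diffusion inside,
# Langmuir-type binding per shell. Tests check it against closed-form
# oracles, not against itself.

paper_regime <- function(...) {
  sim_scenario(mil100(), c_np = 5e-3, guest_conc = 0.1, ...)
}

test_that("guest molecules are conserved through uptake and release", {
  res <- simulate_uptake(paper_regime(duration = 500))
  expect_lt(max(res$mass_balance_error), 1e-6)
  expect_true(all(res$free_external >= 0))
  expect_true(all(res$adsorbed_per_np >= 0))
  rel <- simulate_release(paper_regime(duration = 500), initial_load = 900)
  expect_lt(max(rel$mass_balance_error), 1e-6)
})

test_that("without binding or particles as sinks the trace stays flat", {
  # k_on = 0 and fast internal transport: nothing retains the guest
  sc <- sim_scenario(mil100(), c_np = 5e-3, guest_conc = 0.1,
                     k_on = 0, k_off = 0, d_intra = 1e-10, duration = 300)
  res <- simulate_uptake(sc)
  # only the (negligible) internal pore volume can dilute the bath
  expect_gt(min(res$fluorescence), 1 - 1e-4)
  expect_false(reduce_to_exponential(res)$detected)
})

test_that("the long-time endpoint is the Langmuir fixed point", {
  # parameters chosen so binding-retarded diffusion equilibrates in-run
  sc <- sim_scenario(mil100(), c_np = 5e-3, guest_conc = 0.1,
                     d_intra = 1e-12, site_capacity = 2e3,
                     k_on = 5e-2, k_off = 5e-3, duration = 3000)
  res <- simulate_uptake(sc, n_out = 101)
  eq <- equilibrium_oracle(sc)
  n <- length(res$time)
  expect_equal(res$free_external[n], eq$free_uM, tolerance = 0.01)
  expect_equal(res$adsorbed_per_np[n], eq$adsorbed_per_np, tolerance = 0.01)
  # and the adsorbed amount satisfies the binding isotherm algebraically:
  # occupancy = c / (c + K_D) at the equilibrated free concentration
  occ <- eq$free_uM / (eq$free_uM + sc$k_d_uM)
  expect_equal(res$adsorbed_per_np[n] / sc$site_capacity, occ,
               tolerance = 0.01)
})

test_that("uptake time scales as 1/c_NP in the strong-binding regime", {
  cs <- c(1e-5, 2e-5, 5e-5, 1e-4)   # one decade of particle concentration
  taus <- vapply(cs, function(cnp) {
    sc <- sim_scenario(mil100(), c_np = cnp,
                       guest_conc = 0.1 * cnp / 5e-3,  # fixed guest/NP ratio
                       d_intra = 1e-11, k_on = 5, k_off = 5e-3,
                       duration = 600)
    reduce_to_exponential(simulate_uptake(sc, n_out = 301))$tau
  }, numeric(1))
  fit <- fit_capture_model(cs, taus)
  expect_gt(fit$r_squared, 0.99)
  expect_gte(fit$tau0, 0)
  # prefactor agrees with the Smoluchowski capture-time oracle
  # tau_cap = V_bath / (4 pi D_ex r N_p), i.e. A_cap = tau_cap * c_np
  sp <- mil100()
  a_cap <- 2e-6 / (4 * pi * 3.9e-10 * 26.5e-9 * 2 * sp$np_per_mg)
  expect_gt(fit$prefactor_a / a_cap, 0.8)
  expect_lt(fit$prefactor_a / a_cap, 2.5)
})

test_that("tau0 reflects internal transport: slower pores, larger offset", {
  cs <- c(1e-5, 2e-5, 5e-5, 1e-4)
  tau0_for <- function(d_intra, k_on, k_off) {
    taus <- vapply(cs, function(cnp) {
      sc <- sim_scenario(mil100(), c_np = cnp, guest_conc = 0.1 * cnp / 5e-3,
                         d_intra = d_intra, k_on = k_on, k_off = k_off,
                         duration = 600)
      reduce_to_exponential(simulate_uptake(sc, n_out = 301))$tau
    }, numeric(1))
    fit_capture_model(cs, taus)$tau0
  }
  fast <- tau0_for(3.8e-10, 50, 5e-2)   # near-bulk pores, instant binding
  slow <- tau0_for(1e-13, 5, 5e-3)      # strongly hindered pores
  expect_gt(slow, fast)
  expect_gt(slow, 0)
  expect_lt(fast, 1)                    # offset vanishes with fast internals
})

test_that("doubling the radial resolution leaves the fitted tau unchanged", {
  tau_at <- function(n_shells) {
    sc <- paper_regime(duration = 500, n_shells = n_shells)
    reduce_to_exponential(simulate_uptake(sc))$tau
  }
  expect_equal(tau_at(8L), tau_at(16L), tolerance = 0.01)
})

test_that("release mirrors uptake: no desorption means no release", {
  sc <- paper_regime(k_off = 0, duration = 300)
  rel <- simulate_release(sc, initial_load = 900)
  expect_lt(max(rel$fluorescence), 1e-9)
  expect_error(simulate_release(sc, initial_load = 1e9), "site_capacity")
  expect_error(simulate_release(sc, initial_load = 0), "> 0")
})

test_that("uptake and release relax to the same equilibrium", {
  # same total guest, same bath: the fixed point is unique
  sc <- sim_scenario(mil100(), c_np = 5e-3, guest_conc = 0.1,
                     d_intra = 1e-12, site_capacity = 2e3,
                     k_on = 5e-2, k_off = 5e-3, duration = 6000)
  up <- simulate_uptake(sc, n_out = 61)
  n_p <- sc$c_np * sc$bath_volume * sc$species$np_per_mg
  total_molecules <- sc$guest_conc * 1e-3 * (sc$bath_volume * 1e-6) *
    mof_constants$N_A
  rel <- simulate_release(sc, initial_load = total_molecules / n_p,
                          n_out = 61)
  n <- 61
  expect_equal(rel$free_external[n], up$free_external[n], tolerance = 0.01)
  expect_equal(rel$adsorbed_per_np[n], up$adsorbed_per_np[n],
               tolerance = 0.01)
})

test_that("release is desorption-limited when escape is fast", {
  # hindrance and re-binding both weak: observed rate ~ k_off
  k_off <- 2e-3
  sc <- sim_scenario(mil100(), c_np = 5e-3, guest_conc = 0.1,
                     d_intra = 1e-12, site_capacity = 2e3,
                     k_on = 1e-4, k_off = k_off, duration = 2500)
  rel <- simulate_release(sc, initial_load = 900, n_out = 301)
  # fit the declining retained fraction as a first-order decay
  retained <- data.frame(time_s = rel$time,
                         signal = pmax(1 - rel$fluorescence, 1e-9))
  fit <- fit_exponential(retained)
  expect_true(fit$detected)
  expect_equal(fit$rate, k_off, tolerance = 0.2)
})

test_that("single-exponential reduction flags the regime it fits", {
  good <- reduce_to_exponential(simulate_uptake(paper_regime(duration = 500)))
  expect_true(good$detected)
  expect_gt(good$r_squared, 0.99)
  # a two-timescale trace (fast surface binding + slow interior creep)
  # is described worse by one exponential
  sc2 <- sim_scenario(mil100(), c_np = 5e-3, guest_conc = 0.1,
                      d_intra = 1e-15, site_capacity = 2e3,
                      k_on = 5e-2, k_off = 5e-3, duration = 20000)
  two <- reduce_to_exponential(simulate_uptake(sc2, n_out = 301))
  expect_lt(two$r_squared, good$r_squared)
})

test_that("simulated traces round-trip through the trace CSV format", {
  dir <- withr::local_tempdir()
  res <- simulate_uptake(paper_regime(duration = 300), n_out = 151)
  f <- file.path(dir, "sim.csv")
  write_sim_trace_csv(res, f)
  back <- read_trace_csv(f)
  expect_equal(back$signal, res$fluorescence, tolerance = 1e-12)
  expect_equal(back$time_s, res$time)
})

test_that("scenario validation rejects unphysical input", {
  expect_error(sim_scenario(mil100(), c_np = -1, guest_conc = 0.1), "> 0")
  expect_error(sim_scenario(mil100(), c_np = 1e-3, guest_conc = 0.1,
                            d_intra = 1e-9), "d_intra")
  expect_error(sim_scenario(mil100(), c_np = 1e-3, guest_conc = 0.1,
                            n_shells = 2), "n_shells")
})
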