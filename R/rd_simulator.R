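# Diffusion-immobilization forward model: a well-mixed bath coupled to a
# monodisperse ensemble of porous spherical particles. Guest molecules reach
# a particle at the steady-state diffusive capture rate 4*pi*D_ex*r
# (Smoluchowski), then diffuse radially through the porous interior with the
# hindered coefficient D_intra (method of lines on concentric shells) while
# adsorbing to / desorbing from internal sites with Langmuir-type kinetics
# dS/dt = k_on*c*(S_max - S) - k_off*S. Adsorbed and internal free guest are
# non-fluorescent (quenched), so the observable is the external free
# fraction.

#' Define a simulation scenario
#'
#' @param species a [particle_species()].
#' @param c_np particle mass concentration in the bath, mg/cm^3.
#' @param guest_conc initial external guest concentration, uM (ignored by
#'   [simulate_release()]).
#' @param d_ex external bulk diffusion coefficient, m^2/s.
#' @param d_intra intraparticle diffusion coefficient, m^2/s (< d_ex).
#' @param k_on adsorption rate constant, 1/(uM s).
#' @param k_off desorption rate constant, 1/s. `k_off / k_on` is the
#'   dissociation constant of the internal sites in uM.
#' @param site_capacity adsorption sites per particle (molecules).
#' @param bath_volume bath volume, mL.
#' @param duration simulated time, s.
#' @param n_shells radial shells of the internal discretization (>= 3).
#' @param seed integer; reserved for optional measurement noise, the
#'   dynamics themselves are deterministic.
#' @return A `mof_sim_scenario` list; `$k_d_uM` holds k_off/k_on.
#' @export
#' @examples
#' sp <- particle_species("MIL-100(Fe)", 26.5, 0.98, 2004)
#' sc <- sim_scenario(sp, c_np = 5e-3, guest_conc = 0.1)
sim_scenario <- function(species, c_np, guest_conc = 0.1,
                         d_ex = 3.9e-10, d_intra = 1.5e-11,
                         k_on = 5e-3, k_off = 5e-3,
                         site_capacity = 7e4, bath_volume = 2,
                         duration = 500, n_shells = 8L, seed = 1L) {
  stopifnot(inherits(species, "mof_species"))
  num_pos <- c(c_np = c_np, guest_conc = guest_conc, d_ex = d_ex,
               d_intra = d_intra,
               site_capacity = site_capacity, bath_volume = bath_volume,
               duration = duration)
  if (any(!is.finite(num_pos)) || any(num_pos <= 0))
    stop_input("all physical scenario quantities must be finite and > 0")
  if (k_on < 0 || k_off < 0) stop_input("rate constants must be >= 0")
  if (d_intra >= d_ex)
    stop_input("d_intra must be smaller than d_ex (hindered pore transport)")
  if (n_shells < 3) stop_input("n_shells must be >= 3")
  structure(
    list(species = species, c_np = c_np, guest_conc = guest_conc,
         d_ex = d_ex, d_intra = d_intra, k_on = k_on, k_off = k_off,
         k_d_uM = if (k_on > 0) k_off / k_on else Inf,
         site_capacity = site_capacity, bath_volume = bath_volume,
         duration = duration, n_shells = as.integer(n_shells),
         seed = as.integer(seed)),
    class = "mof_sim_scenario")
}

# shared geometry/derived quantities in SI units
sim_geometry <- function(sc) {
  r <- sc$species$radius_nm * mof_constants$nm_to_m
  n <- sc$n_shells
  edges <- seq(0, r, length.out = n + 1)
  vol <- (4 / 3) * pi * diff(edges^3)             # shell volumes, m^3
  area <- 4 * pi * edges[-c(1, n + 1)]^2          # internal interface areas
  dr <- r / n
  v_p <- (4 / 3) * pi * r^3
  list(
    r = r, n = n, vol = vol, area = area, dr = dr, v_p = v_p,
    v_bath = sc$bath_volume * 1e-6,               # mL -> m^3
    n_particles = sc$c_np * sc$bath_volume * sc$species$np_per_mg,
    k_cap = 4 * pi * sc$d_ex * r,                 # m^3/s per particle
    s_max = sc$site_capacity / (mof_constants$N_A * v_p),  # mol/m^3
    k_on_si = sc$k_on * 1e3,                      # 1/(uM s) -> m^3/(mol s)
    k_off = sc$k_off)
}

sim_rhs <- function(t, y, g) {
  n <- g$n
  cb <- y[1]
  ci <- y[2:(n + 1)]
  si <- y[(n + 2):(2 * n + 1)]

  # internal radial diffusion (finite volume)
  flux <- g$area * g$d_intra * diff(ci) / g$dr    # mol/s across interfaces
  dci <- numeric(n)
  dci[1] <- flux[1] / g$vol[1]
  if (n > 2)
    dci[2:(n - 1)] <- (flux[2:(n - 1)] - flux[1:(n - 2)]) / g$vol[2:(n - 1)]

  # bath <-> outermost shell via the diffusive capture rate
  j_in <- g$k_cap * (cb - ci[n])                  # mol/s per particle
  dci[n] <- (j_in - flux[n - 1]) / g$vol[n]
  dcb <- -g$n_particles * j_in / g$v_bath

  # adsorption/desorption per shell
  bind <- g$k_on_si * ci * (g$s_max - si) - g$k_off * si
  dci <- dci - bind
  dsi <- bind

  list(c(dcb, dci, dsi))
}

sim_run <- function(sc, y0, fluo_ref, n_out = 251L) {
  g <- sim_geometry(sc)
  g$d_intra <- sc$d_intra
  times <- seq(0, sc$duration, length.out = n_out)
  scale <- max(y0, g$s_max, 1e-12)
  sol <- deSolve::ode(y = y0, times = times, func = sim_rhs, parms = g,
                      method = "lsoda", rtol = 1e-10, atol = 1e-14)
  if (attr(sol, "istate")[1] < 0)
    stop_input("reaction-diffusion solver failed to converge")
  y <- sol[, -1, drop = FALSE]
  if (min(y) < -1e-7 * scale)
    stop_input("solver produced negative concentrations; refine tolerances")
  y[y < 0] <- 0

  n <- g$n
  cb <- y[, 1]
  ci <- y[, 2:(n + 1), drop = FALSE]
  si <- y[, (n + 2):(2 * n + 1), drop = FALSE]
  int_free <- as.vector(ci %*% g$vol) / g$v_p      # volume-averaged, mol/m^3
  ads_conc <- as.vector(si %*% g$vol)              # mol per particle
  total <- cb * g$v_bath +
    g$n_particles * (as.vector(ci %*% g$vol) + ads_conc)
  mbe <- abs(total - total[1]) / max(total[1], 1e-300)

  structure(
    list(time = times,
         free_external = cb * 1e3,                 # mol/m^3 -> uM
         free_internal = int_free * 1e3,
         adsorbed_per_np = ads_conc * mof_constants$N_A,
         fluorescence = cb / fluo_ref,
         mass_balance_error = mbe,
         scenario = sc),
    class = "mof_sim_result")
}

#' Simulate guest uptake by a particle suspension
#'
#' Deterministic forward simulation of the diffusion-immobilization model
#' from a guest-only bath: external diffusive capture, hindered internal
#' diffusion, and adsorption to internal sites. The observable fluorescence
#' is the external free concentration normalized to its initial value
#' (internal and adsorbed guest are quenched).
#'
#' @param scenario a [sim_scenario()].
#' @param n_out number of output time points.
#' @return A `mof_sim_result`: `time` (s), `free_external` and
#'   `free_internal` (uM), `adsorbed_per_np` (molecules), `fluorescence`
#'   (normalized), `mass_balance_error` (relative, per time point).
#' @export
#' @examples
#' sp <- particle_species("MIL-100(Fe)", 26.5, 0.98, 2004)
#' res <- simulate_uptake(sim_scenario(sp, c_np = 5e-3, duration = 400))
#' utils::tail(res$fluorescence, 1)
simulate_uptake <- function(scenario, n_out = 251L) {
  g <- sim_geometry(scenario)
  c0 <- scenario$guest_conc * 1e-3               # uM -> mol/m^3
  y0 <- c(c0, rep(0, g$n), rep(0, g$n))
  sim_run(scenario, y0, fluo_ref = c0, n_out = n_out)
}

#' Simulate guest release from pre-loaded particles
#'
#' The same machinery started from a uniformly loaded adsorbed state in a
#' guest-free bath. Fluorescence is normalized to the level the bath would
#' show if the entire initial load were released, so it rises toward the
#' released fraction.
#'
#' @param scenario a [sim_scenario()].
#' @param initial_load adsorbed molecules per particle at t = 0
#'   (<= `site_capacity`).
#' @param n_out number of output time points.
#' @return A `mof_sim_result` (see [simulate_uptake()]).
#' @export
simulate_release <- function(scenario, initial_load, n_out = 251L) {
  if (initial_load <= 0) stop_input("initial_load must be > 0")
  if (initial_load > scenario$site_capacity)
    stop_input("initial_load exceeds site_capacity")
  g <- sim_geometry(scenario)
  s0 <- initial_load / (mof_constants$N_A * g$v_p)  # mol/m^3 of particle
  y0 <- c(0, rep(0, g$n), rep(s0, g$n))
  total_mol <- g$n_particles * initial_load / mof_constants$N_A
  sim_run(scenario, y0, fluo_ref = total_mol / g$v_bath, n_out = n_out)
}

#' @export
print.mof_sim_result <- function(x, ...) {
  cat(sprintf(
    "<mof_sim_result> %d time points over %.3g s; fluorescence %.3g -> %.3g; max |mass balance error| = %.2g\n",
    length(x$time), max(x$time), x$fluorescence[1],
    x$fluorescence[length(x$time)], max(x$mass_balance_error)))
  invisible(x)
}

#' Reduce a simulated trace to a single-exponential fit
#'
#' Converts the simulated fluorescence into a trace and delegates to
#' [fit_exponential()]; the returned `r_squared` lets callers decide whether
#' a single exponential is an adequate description of the regime.
#'
#' @param result a `mof_sim_result`.
#' @return A `mof_decay_fit` (see [fit_exponential()]).
#' @export
reduce_to_exponential <- function(result) {
  tr <- data.frame(time_s = result$time,
                   signal = pmax(result$fluorescence, 1e-12))
  fit_exponential(tr)
}

#' Convert a simulated result to a trace CSV
#'
#' Writes the same `time_s, signal` CSV format [read_trace_csv()] reads.
#'
#' @param result a `mof_sim_result`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_sim_trace_csv <- function(result, path) {
  utils::write.csv(data.frame(time_s = result$time,
                              signal = result$fluorescence),
                   path, row.names = FALSE)
  invisible(path)
}
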