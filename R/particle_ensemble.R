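# Particle-ensemble arithmetic: from TEM sizes and crystallographic density
# to per-particle mass, particles per mg and molar particle concentration.

#' Summarize a nanoparticle size distribution
#'
#' Computes the mean diameter, the coefficient of variation (sd/mean) and the
#' full width at half maximum (FWHM) of a set of projected TEM diameters.
#' The FWHM is read off a Gaussian-kernel density estimate with Silverman's
#' rule-of-thumb bandwidth (`stats::density`, `bw.nrd0`), a fixed documented
#' rule so the summary is deterministic for a given sample.
#'
#' @param diameters numeric vector of particle diameters in nm; at least two
#'   strictly positive values.
#' @return An object of class `mof_size_distribution`: a list with
#'   `mean_diameter` (nm), `sd` (nm), `cv` (dimensionless), `fwhm_lo`,
#'   `fwhm_hi` (nm), `n`.
#' @export
#' @examples
#' d <- gen_sizes(median_nm = 52, sigma_log = 0.31, n = 2000, seed = 1)
#' summarize_sizes(d)
summarize_sizes <- function(diameters) {
  if (!is.numeric(diameters) || length(diameters) < 2)
    stop_input("need at least 2 diameters to summarize a size distribution")
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop_input("all diameters must be finite and > 0 (nm)")

  m  <- mean(diameters)
  s  <- stats::sd(diameters)
  if (s == 0) {
    # degenerate (monodisperse) sample: the density estimate has no width
    return(structure(
      list(mean_diameter = m, sd = 0, cv = 0, fwhm_lo = m, fwhm_hi = m,
           n = length(diameters)),
      class = "mof_size_distribution"))
  }
  de <- stats::density(diameters, bw = "nrd0", n = 2048)
  peak <- which.max(de$y)
  half <- de$y[peak] / 2
  # first crossing of the half-maximum on each side of the mode
  lo_idx <- which(de$y[seq_len(peak)] < half)
  hi_idx <- which(de$y[peak:length(de$y)] < half)
  fwhm_lo <- if (length(lo_idx)) de$x[max(lo_idx)] else NA_real_
  fwhm_hi <- if (length(hi_idx)) de$x[peak + min(hi_idx) - 1L] else NA_real_

  structure(
    list(mean_diameter = m, sd = s, cv = s / m,
         fwhm_lo = fwhm_lo, fwhm_hi = fwhm_hi, n = length(diameters)),
    class = "mof_size_distribution"
  )
}

#' @export
print.mof_size_distribution <- function(x, ...) {
  cat(sprintf(
    "Size distribution (n = %d): mean %.1f nm (sigma = %.0f%%, FWHM %.1f-%.1f nm)\n",
    x$n, x$mean_diameter, 100 * x$cv, x$fwhm_lo, x$fwhm_hi))
  invisible(x)
}

#' Mass of a single spherical nanoparticle
#'
#' `m = (4/3) pi r^3 rho` with the unit conversions (nm, g/cm^3 -> g)
#' handled internally.
#'
#' @param radius particle radius in nm.
#' @param density crystallographic mass density in g/cm^3.
#' @return Mass of one particle in grams.
#' @export
#' @examples
#' particle_mass(26.5, 0.98) # ~7.6e-17 g, a MIL-100(Fe)-sized particle
particle_mass <- function(radius, density) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop_input("radius must be finite and > 0 (nm)")
  if (any(!is.finite(density)) || any(density <= 0))
    stop_input("density must be finite and > 0 (g/cm^3)")
  r_cm <- radius * 1e-7            # nm -> cm, so r^3 * (g/cm^3) is grams
  (4 / 3) * pi * r_cm^3 * density
}

#' Number density of nanoparticles per milligram
#'
#' @param mass_per_np mass of one particle in grams.
#' @return A list with `np_per_mg` (particles per mg of carrier) and
#'   `molar_pmol_per_mg` (the same count expressed in pmol).
#' @export
#' @examples
#' number_density(7.6e-17)
number_density <- function(mass_per_np) {
  if (any(!is.finite(mass_per_np)) || any(mass_per_np <= 0))
    stop_input("mass_per_np must be finite and > 0 (g)")
  n <- mof_constants$mg_to_g / mass_per_np
  list(np_per_mg = n,
       molar_pmol_per_mg = n / mof_constants$N_A * 1e12)
}

#' Define a nanoparticle species
#'
#' Bundles the TEM mean radius, the crystallographic density and (optionally)
#' the BET surface area of one carrier material, and derives the per-particle
#' mass, the particle count per mg and the molar particle concentration
#' per mg.
#'
#' @param name label, e.g. `"MIL-100(Fe)"`.
#' @param radius_nm mean particle radius in nm.
#' @param density_g_cm3 crystallographic density in g/cm^3.
#' @param s_bet_m2_g optional BET surface area in m^2/g.
#' @return An object of class `mof_species`: a list with the inputs plus
#'   `mass_per_np` (g), `np_per_mg` (1/mg), `molar_pmol_per_mg` (pmol/mg).
#' @export
#' @examples
#' mil100 <- particle_species("MIL-100(Fe)", radius_nm = 26.5,
#'                            density_g_cm3 = 0.98, s_bet_m2_g = 2004)
#' mil100$np_per_mg # ~1.31e13
particle_species <- function(name, radius_nm, density_g_cm3,
                             s_bet_m2_g = NULL) {
  m  <- particle_mass(radius_nm, density_g_cm3)
  nd <- number_density(m)
  structure(
    list(name = name, radius_nm = radius_nm,
         density_g_cm3 = density_g_cm3,
         s_bet_m2_g = s_bet_m2_g,
         mass_per_np = m,
         np_per_mg = nd$np_per_mg,
         molar_pmol_per_mg = nd$molar_pmol_per_mg),
    class = "mof_species"
  )
}

#' @export
print.mof_species <- function(x, ...) {
  cat(sprintf("<mof_species> %s\n", x$name))
  cat(sprintf("  r = %.3g nm, rho = %.3g g/cm^3\n", x$radius_nm, x$density_g_cm3))
  cat(sprintf("  mass/NP = %.3g g, %.3g NPs/mg (%.3g pmol/mg)\n",
              x$mass_per_np, x$np_per_mg, x$molar_pmol_per_mg))
  if (!is.null(x$s_bet_m2_g))
    cat(sprintf("  S_BET = %.4g m^2/g\n", x$s_bet_m2_g))
  invisible(x)
}

#' Read species definitions from a key-value config file
#'
#' The file is YAML: a list of entries each with `name`, `radius_nm`,
#' `density_g_cm3` and optional `s_bet_m2_g`.
#'
#' @param path path to the YAML file.
#' @return A named list of [particle_species()] objects.
#' @export
read_species_config <- function(path) {
  if (!file.exists(path)) stop_input("species config not found: ", path)
  entries <- yaml::read_yaml(path)
  if (length(entries) == 0) stop_input("species config is empty: ", path)
  out <- lapply(entries, function(e) {
    for (f in c("name", "radius_nm", "density_g_cm3"))
      if (is.null(e[[f]])) stop_input("species entry missing field '", f, "'")
    particle_species(e$name, as.numeric(e$radius_nm),
                     as.numeric(e$density_g_cm3),
                     if (!is.null(e$s_bet_m2_g)) as.numeric(e$s_bet_m2_g))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Read raw TEM diameters from CSV
#'
#' Expects a single column headed `diameter_nm`.
#'
#' @param path CSV path.
#' @return Numeric vector of diameters (nm).
#' @export
read_diameters_csv <- function(path) {
  if (!file.exists(path)) stop_input("diameter CSV not found: ", path)
  df <- utils::read.csv(path)
  if (!"diameter_nm" %in% names(df))
    stop_input("diameter CSV must have a 'diameter_nm' column: ", path)
  as.numeric(df$diameter_nm)
}
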