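# Langmuir sorption equilibrium: absorbance calibration, depletion
# accounting, nonlinear Langmuir fit and payload bookkeeping.

#' Evaluate the Langmuir sorption isotherm
#'
#' `P(c) = P_max * c / (c + K_D)`: the adsorbed payload at external guest
#' concentration `c`, for a finite set of identical binding sites. `K_D` is
#' the concentration at which half of the maximal payload is adsorbed.
#'
#' @param c external guest concentration, ug/mL (vectorized, >= 0).
#' @param p_max saturation payload, ug per mg carrier.
#' @param k_d dissociation constant, ug/mL (> 0).
#' @return Adsorbed payload in ug per mg carrier.
#' @export
#' @examples
#' langmuir_eval(4.4, p_max = 649.4, k_d = 4.4) # half saturation
langmuir_eval <- function(c, p_max, k_d) {
  if (any(!is.finite(c)) || any(c < 0))
    stop_input("concentrations must be finite and >= 0")
  if (!is.finite(k_d) || k_d <= 0) stop_input("k_d must be > 0")
  p_max * c / (c + k_d)
}

#' Fit a linear absorbance calibration A = m*c + t
#'
#' Ordinary least squares on a dilution series; the intercept is retained
#' rather than forced through zero because real instrument baselines are
#' non-zero.
#'
#' @param conc_ug_ml concentrations of the dilution series, ug/mL.
#' @param absorbance integrated absorbance (dimensionless).
#' @return List with `slope`, `intercept`, `r_squared`, and
#'   `to_conc(absorbance)`, the inverse mapping.
#' @export
fit_calibration <- function(conc_ug_ml, absorbance) {
  stopifnot(length(conc_ug_ml) == length(absorbance))
  if (length(conc_ug_ml) < 3)
    stop_input("calibration needs at least 3 points")
  fit <- stats::lm(absorbance ~ conc_ug_ml)
  co <- stats::coef(fit)
  slope <- unname(co[2]); intercept <- unname(co[1])
  if (!is.finite(slope) || slope <= 0)
    stop_input("calibration slope must be positive")
  list(slope = slope, intercept = intercept,
       # noise-free dilution series are legitimate; silence the perfect-fit
       # warning from summary.lm
       r_squared = suppressWarnings(summary(fit)$r.squared),
       to_conc = function(a) (a - intercept) / slope)
}

#' Adsorbed amount from stock/supernatant depletion
#'
#' Converts paired absorbances of the stock solution and of the supernatant
#' recovered after centrifuging out the carriers into adsorbed ug per mg of
#' carrier, via a linear calibration.
#'
#' @param a_stock,a_supernatant integrated absorbances.
#' @param calibration result of [fit_calibration()].
#' @param volume_ml incubation volume, mL.
#' @param carrier_mass_mg carrier mass, mg.
#' @return Adsorbed amount, ug per mg (negative depletion is clipped at 0).
#' @export
depletion_to_adsorbed <- function(a_stock, a_supernatant, calibration,
                                  volume_ml, carrier_mass_mg) {
  if (any(carrier_mass_mg <= 0) || any(volume_ml <= 0))
    stop_input("volume and carrier mass must be > 0")
  dc <- calibration$to_conc(a_stock) - calibration$to_conc(a_supernatant)
  pmax(dc, 0) * volume_ml / carrier_mass_mg
}

#' Construct an isotherm dataset
#'
#' @param concentrations external guest concentrations, ug/mL.
#' @param adsorbed adsorbed payloads, ug per mg carrier.
#' @param replicate_sd optional per-point standard deviations, ug per mg.
#' @param carrier_mass_mg carrier mass used, mg (metadata).
#' @return A `mof_isotherm` data.frame with attributes.
#' @export
isotherm_dataset <- function(concentrations, adsorbed, replicate_sd = NULL,
                             carrier_mass_mg = 1) {
  if (length(concentrations) != length(adsorbed))
    stop_input("concentrations and adsorbed must have equal length")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop_input("concentrations must be finite and >= 0")
  if (any(!is.finite(adsorbed)) || any(adsorbed < 0))
    stop_input("adsorbed amounts must be finite and >= 0")
  df <- data.frame(conc_ug_ml = concentrations,
                   adsorbed_ug_per_mg = adsorbed)
  if (!is.null(replicate_sd)) df$sd <- replicate_sd
  attr(df, "carrier_mass_mg") <- carrier_mass_mg
  class(df) <- c("mof_isotherm", "data.frame")
  df
}

#' Fit the Langmuir model to a depletion isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt, positive bounds) for
#' `P(c) = P_max c / (c + K_D)`. When per-point standard deviations are
#' absent the fit uses relative (proportional) weights, because loading
#' designs typically span about two decades of concentration and absolute
#' residuals would be dominated by the saturated points. Initial guesses:
#' `P_max = max(adsorbed)`, `K_D = ` the design concentration closest to
#' half of that.
#'
#' @param data a `mof_isotherm` (see [isotherm_dataset()]) or a data.frame
#'   with columns `conc_ug_ml` and `adsorbed_ug_per_mg` (optional `sd`).
#' @param m_guest molar mass of the guest, g/mol (used to populate the molar
#'   fields; 412.3 g/mol is fluorescein disodium).
#' @return An object of class `mof_langmuir_fit`: `p_max` (ug/mg),
#'   `k_d_mass` (ug/mL), `k_d_molar` (uM), `p_max_molar` (umol/mg),
#'   `se_p_max`, `se_k_d`, `residual_norm`, `converged`, `m_guest`.
#'   Degenerate data (no concentration dependence, non-convergence, or a
#'   non-positive estimate) returns `converged = FALSE` with a `reason` —
#'   never a silent NaN.
#' @export
#' @examples
#' iso <- gen_isotherm(p_max = 649.4, k_d = 4.4,
#'                     design = c(5, 10, 20, 50, 150, 400, 1000, 1500),
#'                     noise = noise_model(0, 0, seed = 1))
#' fit_langmuir(iso, m_guest = 412.3)
fit_langmuir <- function(data, m_guest = 412.3) {
  c_ <- data$conc_ug_ml
  y  <- data$adsorbed_ug_per_mg
  if (length(unique(c_[c_ > 0])) < 3)
    stop_input("need at least 3 distinct positive concentrations")

  fail <- function(reason) structure(
    list(converged = FALSE, reason = reason, m_guest = m_guest),
    class = "mof_langmuir_fit")

  if (stats::sd(y) == 0 || max(y) <= 0)
    return(fail("adsorbed amounts carry no concentration dependence"))

  p0 <- max(y)
  k0 <- c_[which.min(abs(y - p0 / 2))]
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(c_[c_ > 0])

  w <- if (!is.null(data$sd) && all(data$sd > 0)) {
    1 / data$sd^2
  } else {
    # proportional weighting; floor avoids infinite weight at c = 0
    1 / pmax(y, 0.05 * max(y))^2
  }

  df <- data.frame(c_ = c_, y = y, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ p_max * c_ / (c_ + k_d),
      data = df,
      start = list(p_max = p0, k_d = k0),
      lower = c(p_max = 1e-12, k_d = 1e-12),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))

  est <- stats::coef(fit)
  se  <- tryCatch(sqrt(diag(stats::vcov(fit))),
                  error = function(e) c(NA_real_, NA_real_))
  if (any(!is.finite(est)) || any(est <= 0))
    return(fail("non-positive parameter estimate"))
  # K_D pushed beyond the design range means the data never bend over
  if (est["k_d"] > 10 * max(c_))
    return(fail("K_D unbounded: no saturation within the design range"))

  res <- stats::resid(fit) * sqrt(w)
  structure(
    list(p_max = unname(est["p_max"]),
         k_d_mass = unname(est["k_d"]),
         k_d_molar = ugml_to_uM(unname(est["k_d"]), m_guest),
         p_max_molar = ug_to_umol(unname(est["p_max"]), m_guest),
         se_p_max = unname(se[1]), se_k_d = unname(se[2]),
         residual_norm = sqrt(sum(res^2)),
         converged = TRUE, m_guest = m_guest),
    class = "mof_langmuir_fit")
}

#' @export
print.mof_langmuir_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<mof_langmuir_fit> FAILED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<mof_langmuir_fit> P_max = %.4g ug/mg (%.3g umol/mg), K_D = %.3g ug/mL (%.3g uM)\n",
              x$p_max, x$p_max_molar, x$k_d_mass, x$k_d_molar))
  invisible(x)
}

#' Payload bookkeeping for a fitted isotherm
#'
#' Derives, from a Langmuir fit and a particle species, the number of guest
#' molecules adsorbed per nanoparticle at saturation, the weight-payload
#' ratio (guest mass / carrier mass), and — when a BET surface area is
#' available — the internal surface area occupied per guest molecule.
#'
#' @param fit a converged [fit_langmuir()] result, or a list with `p_max`
#'   (ug/mg) and `p_max_molar` (umol/mg).
#' @param species a [particle_species()].
#' @return An object of class `mof_payload_summary`: `molecules_per_np`,
#'   `weight_ratio_pct`, `area_per_molecule_nm2` (NA when `s_bet` is
#'   missing), `m_guest`.
#' @export
#' @examples
#' mil100 <- particle_species("MIL-100(Fe)", 26.5, 0.98, s_bet_m2_g = 2004)
#' fit <- list(p_max = 649.4, p_max_molar = 649.4 / 412.3,
#'             m_guest = 412.3, converged = TRUE)
#' payload_summary(fit, mil100)
payload_summary <- function(fit, species) {
  if (!isTRUE(fit$converged))
    stop_input("payload_summary requires a converged Langmuir fit")
  n_molecules_per_mg <- fit$p_max_molar * 1e-6 * mof_constants$N_A
  area <- if (is.null(species$s_bet_m2_g)) NA_real_ else {
    # m^2 per mg of carrier over molecules per mg -> m^2, then to nm^2
    (species$s_bet_m2_g * mof_constants$mg_to_g) / n_molecules_per_mg * 1e18
  }
  structure(
    list(molecules_per_np = n_molecules_per_mg / species$np_per_mg,
         weight_ratio_pct = fit$p_max / 1000 * 100,
         area_per_molecule_nm2 = area,
         m_guest = fit$m_guest,
         species = species$name),
    class = "mof_payload_summary")
}

#' @export
print.mof_payload_summary <- function(x, ...) {
  cat(sprintf("<mof_payload_summary> %s: %.3g molecules/NP, weight ratio %.0f%%",
              x$species, x$molecules_per_np, x$weight_ratio_pct))
  if (is.finite(x$area_per_molecule_nm2))
    cat(sprintf(", %.2g nm^2 per molecule", x$area_per_molecule_nm2))
  cat("\n")
  invisible(x)
}

#' Read an isotherm CSV
#'
#' Columns: `conc_ug_ml, adsorbed_ug_per_mg[, sd]`.
#'
#' @param path CSV path.
#' @return A `mof_isotherm` dataset.
#' @export
read_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop_input("isotherm CSV not found: ", path)
  df <- utils::read.csv(path)
  need <- c("conc_ug_ml", "adsorbed_ug_per_mg")
  if (!all(need %in% names(df)))
    stop_input("isotherm CSV must have columns ", paste(need, collapse = ", "),
               ": ", path)
  isotherm_dataset(df$conc_ug_ml, df$adsorbed_ug_per_mg,
                   replicate_sd = df$sd)
}
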