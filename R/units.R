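# Internal unit system is SI (m, kg, s, mol). All user-facing functions
# accept and report the bench units common in the nanocarrier literature
# (nm, g/cm^3, ug/mL, uM, pmol, mg) and convert at the boundary through the
# constants below, so no conversion factor ever appears inline in a formula.

#' Physical constants and unit conversion factors
#'
#' Avogadro's number and the conversion factors used at the package
#' boundaries. Exported so that analysis scripts can reuse exactly the same
#' values instead of retyping literals.
#'
#' @format A named list:
#' \describe{
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{nm_to_m}{metres per nanometre.}
#'   \item{g_cm3_to_kg_m3}{kg/m^3 per g/cm^3.}
#'   \item{ug_ml_to_g_l}{g/L per ug/mL (identity in value: 1 ug/mL = 1 mg/L
#'     = 1e-3 g/L).}
#'   \item{mg_to_g}{grams per milligram.}
#' }
#' @export
#' @examples
#' mof_constants$N_A
mof_constants <- list(
  N_A          = 6.02214076e23,
  nm_to_m      = 1e-9,
  g_cm3_to_kg_m3 = 1e3,
  ug_ml_to_g_l = 1e-3,
  mg_to_g      = 1e-3
)

#' Convert a mass concentration to a molar concentration
#'
#' @param c_ug_ml concentration in ug/mL.
#' @param m_guest molar mass of the guest in g/mol.
#' @return Concentration in uM.
#' @export
#' @examples
#' ugml_to_uM(4.4, 412.3) # ~10.7 uM
ugml_to_uM <- function(c_ug_ml, m_guest) {
  stopifnot(is.numeric(c_ug_ml), is.numeric(m_guest), all(m_guest > 0))
  # ug/mL == mg/L; mg/L / (g/mol) = mmol/L * 1e-3 = umol/L * ... work it out:
  # (c_ug_ml * 1e-3 g/L) / m_guest g/mol = mol/L * 1e-3/m -> *1e6 = uM
  c_ug_ml * mof_constants$ug_ml_to_g_l / m_guest * 1e6
}

#' Convert a mass payload to a molar payload
#'
#' @param p_ug_per_mg payload in ug guest per mg carrier.
#' @param m_guest molar mass of the guest in g/mol.
#' @return Payload in umol per mg carrier.
#' @export
#' @examples
#' ug_to_umol(649.4, 412.3) # ~1.58 umol/mg
ug_to_umol <- function(p_ug_per_mg, m_guest) {
  stopifnot(all(m_guest > 0))
  p_ug_per_mg / m_guest
}

# fail with the caller-facing message used across the package
stop_input <- function(...) stop(..., call. = FALSE)
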