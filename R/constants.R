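# Internal unit system:
#   length cm, time s, volume cm^3 (mL), amount umol.
#   1 mM = 1 umol/cm^3, so permeability [cm/s] * concentration [mM]
#   gives a solute flux in umol/(s*cm^2), and volume flow [cm^3/s] *
#   concentration [mM] gives a solute flow in umol/s.

#' Physical constants and unit conversions used throughout the model
#'
#' @format A list with elements:
#' \describe{
#'   \item{RT_F}{Thermal voltage RT/F at 310 K, in mV (26.7).}
#'   \item{VW}{Partial molar volume of water, cm^3/umol (18e-6).}
#'   \item{VISCOSITY}{Tubular fluid viscosity, g cm^-1 s^-1.}
#'   \item{MMHG_DYN}{dyn/cm^2 per mmHg.}
#'   \item{NL_MIN_TO_ML_S}{Convert nL/min to cm^3/s.}
#'   \item{ML_S_TO_L_DAY}{Convert cm^3/s to L/day.}
#'   \item{UMOL_S_TO_MMOL_DAY}{Convert umol/s to mmol/day.}
#' }
#' @keywords internal
.ns_const <- list(
  RT_F = 26.7,
  VW = 18e-6,
  VISCOSITY = 7.2e-3,
  MMHG_DYN = 1333.22,
  NL_MIN_TO_ML_S = 1e-6 / 60,
  ML_S_TO_L_DAY = 86.4,
  UMOL_S_TO_MMOL_DAY = 86.4,
  UMOL_S_TO_MOL_DAY = 0.0864
)

# Solute bookkeeping: fixed order everywhere in the package.
.ns_solutes <- c("Na", "K", "Cl", "urea", "glucose")
.ns_valence <- c(Na = 1, K = 1, Cl = -1, urea = 0, glucose = 0)

# Luminal species: the five transported solutes plus a non-reacting
# background anion ("anion", a bicarbonate-buffer proxy) that closes
# luminal electroneutrality. It is consumed by NHE3's proton secretion
# (titration of the buffer) and otherwise moves only paracellularly.
.ns_lum <- c(.ns_solutes, "anion")
.ns_lum_valence <- c(.ns_valence, anion = -1)

#' Solute table
#'
#' The five transported solutes of the core model, their valences and
#' default (non-diabetic) plasma concentrations in mM.
#'
#' @return A data.frame with columns `name`, `valence`, `plasma_mM`.
#' @export
#' @examples
#' solute_table()
solute_table <- function() {
  data.frame(
    name = .ns_solutes,
    valence = unname(.ns_valence),
    plasma_mM = c(140, 5, 113, 5, 5),
    stringsAsFactors = FALSE
  )
}
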