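# Transmembrane and paracellular flux laws.
#
# Sign convention: positive flux = movement from the cis (first) compartment
# to the trans compartment; at the tubule wall, positive = reabsorption
# (lumen -> cell/interstitium). All area-specific solute fluxes are in
# umol/(s*cm^2); water fluxes in cm/s (volume per area per time).

#' Sodium-glucose cotransporter flux (SGLT2 / SGLT1)
#'
#' Reversible, electrogenic saturable carrier with Hill-type occupancy in
#' glucose and Na:
#' `J_glu = vmax_eff * (f_lumen - f_cell * exp(-n*Va/(RT/F)))` where
#' `f = g/(g+Km_g) * (Na/(Na+Km_Na))^n`, `n` is the Na:glucose
#' stoichiometry (1 for SGLT2, 2 for SGLT1) and `Va` is the apical
#' membrane potential (lumen minus cell): the Boltzmann factor of the n
#' translocated Na+ charges lets the carrier accumulate glucose against
#' its chemical gradient, as the cell-interior-negative potential does in
#' the proximal tubule. The coupled Na flux is `n * J_glu`;
#' `vmax_eff = vmax * (1 - inhibition_fraction)`.
#'
#' @param kind "SGLT2" or "SGLT1".
#' @param lumen,cell Lists with `na` and `glucose` concentrations (mM).
#' @param act List with `vmax` (umol s^-1 cm^-2), `km_glucose`, `km_na`
#'   (mM) and optional `inhibition_fraction` (0-1, default 0).
#' @param va_mV Apical membrane potential, lumen minus cell (mV);
#'   0 gives the purely chemical carrier.
#' @return Named numeric vector `c(glucose=, na=)`.
#' @export
#' @examples
#' a <- list(vmax = 1e-3, km_glucose = 2, km_na = 30)
#' sglt_flux("SGLT2", list(na = 140, glucose = 5), list(na = 15, glucose = 1), a)
sglt_flux <- function(kind = c("SGLT2", "SGLT1"), lumen, cell, act,
                      va_mV = 0) {
  kind <- match.arg(kind)
  n <- if (kind == "SGLT2") 1 else 2
  if (any(c(lumen$na, lumen$glucose, cell$na, cell$glucose) < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  inh <- if (is.null(act$inhibition_fraction)) 0 else act$inhibition_fraction
  stopifnot(inh >= 0, inh <= 1)
  occ <- function(g, na)
    g / (g + act$km_glucose) * (na / (na + act$km_na))^n
  jg <- act$vmax * (1 - inh) *
    (occ(lumen$glucose, lumen$na) -
       occ(cell$glucose, cell$na) * exp(-n * va_mV / .ns_const$RT_F))
  c(glucose = jg, na = n * jg)
}

#' Facilitated glucose carrier flux (GLUT1 / GLUT2)
#'
#' Symmetric saturable carrier:
#' `J = vmax * (S_cis/(Km+S_cis) - S_trans/(Km+S_trans))`.
#'
#' @param cis,trans Glucose concentrations (mM).
#' @param act List with `vmax` and `km`.
#' @return Glucose flux, umol/(s*cm^2), positive cis -> trans.
#' @export
glut_flux <- function(cis, trans, act) {
  if (cis < 0 || trans < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  act$vmax * (cis / (cis + act$km) - trans / (trans + act$km))
}

#' Generic electroneutral cotransporter flux
#'
#' Reversible saturable carrier for coupled, electroneutral cotransport.
#' The cycle flux is `vmax * (f_cis - f_trans)` where `f` is the product of
#' Michaelis occupancies of every transported substrate raised to its
#' stoichiometric coefficient. Used for NKCC2 (1 Na : 1 K : 2 Cl),
#' NCC (1 Na : 1 Cl) and K-Cl cotransport (1 K : 1 Cl).
#'
#' @param stoich Named integer vector of stoichiometric coefficients
#'   (names are solute names matching `cis`/`trans`/`km`).
#' @param cis,trans Named concentration vectors (mM).
#' @param act List with `vmax` and `km` (named vector of affinities, mM).
#' @return List with `cycle` (cycle flux) and `fluxes` (named per-solute
#'   fluxes = stoich * cycle, positive cis -> trans).
#' @export
cotransport_flux <- function(stoich, cis, trans, act) {
  s <- names(stoich)
  if (any(cis[s] < 0) || any(trans[s] < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  occ <- function(cc) prod((cc[s] / (cc[s] + act$km[s]))^stoich)
  cyc <- act$vmax * (occ(cis) - occ(trans))
  list(cycle = cyc, fluxes = stoich * cyc)
}

#' NKCC2 flux (1 Na : 1 K : 2 Cl)
#' @param lumen,cell Named concentration vectors with `Na`, `K`, `Cl` (mM).
#' @param act List with `vmax` and `km` (named: Na, K, Cl).
#' @return List with `cycle` and per-solute `fluxes`.
#' @export
nkcc2_flux <- function(lumen, cell, act)
  cotransport_flux(c(Na = 1, K = 1, Cl = 2), lumen, cell, act)

#' NCC flux (1 Na : 1 Cl)
#' @inheritParams nkcc2_flux
#' @export
ncc_flux <- function(lumen, cell, act)
  cotransport_flux(c(Na = 1, Cl = 1), lumen, cell, act)

#' K-Cl cotransport flux (1 K : 1 Cl), basolateral efflux pathway
#' @param cell,bath Named concentration vectors with `K`, `Cl` (mM).
#' @param act List with `vmax` and `km` (named: K, Cl).
#' @export
kcl_flux <- function(cell, bath, act)
  cotransport_flux(c(K = 1, Cl = 1), cell, bath, act)

#' NHE3 flux (apical Na entry with a fixed-pH proxy)
#'
#' Na/H exchange is represented as saturable Na entry biased by a fixed
#' proton-side occupancy factor `beta` (< 1 gives net lumen-to-cell Na
#' movement at equal Na): `J = vmax * (occ(Na_lumen) - beta * occ(Na_cell))`.
#' Its equilibrium is where the two occupancy terms balance, reflecting the
#' implicit transmembrane proton gradient.
#'
#' @param lumen_na,cell_na Na concentrations (mM).
#' @param act List with `vmax`, `km`, `beta`.
#' @return Na flux, positive lumen -> cell.
#' @export
nhe3_flux <- function(lumen_na, cell_na, act) {
  if (lumen_na < 0 || cell_na < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  act$vmax * (lumen_na / (lumen_na + act$km) -
                act$beta * cell_na / (cell_na + act$km))
}

#' Goldman-Hodgkin-Katz channel flux
#'
#' Constant-field electrodiffusive flux for charged solutes; reduces to
#' Fickian diffusion `P*(c_cis - c_trans)` for neutral solutes and in the
#' zero-potential limit.
#'
#' @param valence Integer charge of the solute.
#' @param cis,trans Concentrations (mM).
#' @param dv_mV Potential of the cis side relative to the trans side (mV).
#' @param p Permeability (cm/s).
#' @return Flux, umol/(s*cm^2), positive cis -> trans.
#' @export
channel_flux_ghk <- function(valence, cis, trans, dv_mV, p) {
  if (p < 0) stop("permeability must be non-negative", call. = FALSE)
  phi <- valence * dv_mV / .ns_const$RT_F
  if (abs(phi) < 1e-7) return(p * (cis - trans))
  e <- exp(-phi)
  p * phi * (cis - trans * e) / (1 - e)
}

#' Na/K-ATPase pump flux
#'
#' Pump cycle rate `vmax * (Na_cell/(Na_cell+Km))^3`, exporting 3 Na and
#' importing 2 K per cycle. The cycle rate feeds the active-transport
#' accounting of total sodium transport.
#'
#' @param cell_na Cytosolic Na (mM).
#' @param act List with `vmax` (cycle capacity) and `km`.
#' @return List with `cycle`, `na_efflux` (= 3*cycle) and
#'   `k_influx` (= 2*cycle).
#' @export
nak_atpase_flux <- function(cell_na, act) {
  if (cell_na < 0) stop("cell Na must be non-negative", call. = FALSE)
  cyc <- act$vmax * (cell_na / (cell_na + act$km))^3
  list(cycle = cyc, na_efflux = 3 * cyc, k_influx = 2 * cyc)
}

#' Paracellular flux across the tight junction
#'
#' Sum of a convective solvent-drag term `(1 - sigma) * Jv * c_lm`, with
#' `c_lm` the logarithmic mean of the two concentrations, and a GHK (or
#' Fickian, for neutral solutes) diffusive term. Positive = lumen ->
#' interstitium (reabsorption).
#'
#' @param valence Integer charge.
#' @param lumen,interstitium Concentrations (mM).
#' @param dv_mV Transepithelial potential, lumen minus interstitium (mV).
#' @param jv Paracellular water flux (cm/s), positive reabsorptive.
#' @param p Paracellular permeability (cm/s).
#' @param sigma Reflection coefficient (0-1).
#' @return Flux, umol/(s*cm^2).
#' @export
paracellular_flux <- function(valence, lumen, interstitium, dv_mV, jv, p,
                              sigma) {
  stopifnot(sigma >= 0, sigma <= 1)
  drag <- (1 - sigma) * jv * log_mean(lumen, interstitium)
  drag + channel_flux_ghk(valence, lumen, interstitium, dv_mV, p)
}

log_mean <- function(a, b) {
  if (a <= 0 || b <= 0) return(max(0, (a + b) / 2))
  if (abs(a - b) < 1e-12 * (a + b)) return((a + b) / 2)
  (a - b) / log(a / b)
}

#' Osmotic water flux
#'
#' `Jv = Pf * Vw * sum_i sigma_i * (c_bath_i - c_lumen_i)`, optionally with
#' a hydraulic term `Lp_dP * (P_lumen - P_bath)`. Positive = reabsorption.
#'
#' @param c_lumen,c_bath Concentration vectors (mM).
#' @param pf Osmotic water permeability (cm/s).
#' @param sigma Reflection coefficients (scalar or vector; default 1).
#' @param dP_mmHg Hydrostatic pressure difference lumen minus bath (mmHg).
#' @param lp_dP Hydraulic conductivity for the pressure term
#'   (cm s^-1 mmHg^-1; default 0, osmotic-only).
#' @return Volume flux, cm/s.
#' @export
water_flux <- function(c_lumen, c_bath, pf, sigma = 1, dP_mmHg = 0,
                       lp_dP = 0) {
  if (pf < 0) stop("Pf must be non-negative", call. = FALSE)
  pf * .ns_const$VW * sum(sigma * (c_bath - c_lumen)) + lp_dP * dP_mmHg
}

#' Flow(torque)-dependent scaling of proximal transcellular transport
#'
#' Microvillous-drag proxy: torque `tau` is proportional to `mu*Q/r^2`, and
#' the transporter density multiplier is
#' `1 + C_T * (tau/tau_ref - 1)`, clamped to `[0.2, 3]`. Applied to the
#' transcellular transporters of the proximal segments only, never to the
#' paracellular pathway.
#'
#' @param q,q_ref Local and reference volume flows (same units).
#' @param r,r_ref Local and reference tubule radii.
#' @param c_t Sensitivity (dimensionless; 0 disables the effect).
#' @param clamp Two-element vector of multiplier bounds.
#' @return Dimensionless multiplier.
#' @export
#' @examples
#' torque_scaling(1.5, 1, 1, 1, c_t = 1.2)  # high flow -> multiplier > 1
torque_scaling <- function(q, q_ref, r, r_ref, c_t, clamp = c(0.2, 3)) {
  if (any(c(q, q_ref, r, r_ref) <= 0))
    stop("flows and radii must be positive", call. = FALSE)
  tau_rel <- (q / q_ref) * (r_ref / r)^2
  m <- 1 + c_t * (tau_rel - 1)
  min(max(m, clamp[1]), clamp[2])
}
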