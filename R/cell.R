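# Steady-state epithelial cell compartment.
#
# At every grid point of a cell-bearing segment the model solves a 7-unknown
# algebraic system: five cytosolic concentrations (Na, K, Cl, urea, glucose),
# the cell potential V_cell and the transepithelial potential V_te (both
# relative to the interstitium). Equations: per-solute steady state
# (apical influx = basolateral efflux), cell electroneutrality against a
# fixed impermeant cytosolic anion, and zero net transepithelial current
# (open circuit). Transcellular charge conservation is implied by the
# per-solute balances.

# Fast inline GHK; dv already divided by RT/F is NOT used -- dv in mV.
.ghk <- function(z, c1, c2, dv, p) {
  phi <- z * dv / 26.7
  if (!is.finite(phi) || abs(phi) < 1e-7) return(p * (c1 - c2))
  e <- exp(-phi)
  p * phi * (c1 - c2 * e) / (1 - e)
}

.logmean <- function(a, b) {
  if (a <= 1e-12 || b <= 1e-12) return(max(0, (a + b) / 2))
  if (abs(a - b) < 1e-9 * (a + b)) return((a + b) / 2)
  (a - b) / log(a / b)
}

# Evaluate the cell system.
# x: c(cNa,cK,cCl,cUrea,cGlu, v_cell, v_te); cl, cs: luminal/interstitial
# concentrations (len 5); sp: compiled segment spec; tq: torque multiplier
# for transcellular transporters; pumpfac: axial Na/K-ATPase factor.
# Returns numeric(7) residual, or a full flux breakdown if want_flux.
cell_eval <- function(x, cl, cs, sp, tq = 1, pumpfac = 1, want_flux = FALSE) {
  cc <- x[1:5]
  vc <- x[6]
  vt <- x[7]
  va <- vt - vc          # lumen minus cell
  vb <- vc               # cell minus interstitium (interstitium = 0)

  # water fluxes (lumen -> interstitium positive); background osmoles cancel
  osmL <- cl[1] + cl[2] + cl[3] + cl[4] + cl[5] + cl[6]
  osmS <- cs[1] + cs[2] + cs[3] + cs[4] + cs[5] + cs[6]
  jv_t <- sp$pf_trans * 18e-6 * (osmS - osmL)
  jv_p <- sp$pf_para * 18e-6 * sum(sp$sigma * (cs - cl))

  ja <- numeric(5)   # apical, lumen -> cell
  jb <- numeric(5)   # basolateral, cell -> interstitium
  pump_cycle <- 0
  jsglt <- 0
  jnhe3 <- 0

  # --- apical ---
  if (sp$v_nhe3 > 0) {
    # forward rate limited by the luminal buffer anion: the secreted
    # proton titrates one buffer equivalent per Na+ absorbed
    buf <- cl[6] / (cl[6] + sp$km_buf)
    jnhe3 <- tq * sp$v_nhe3 *
      (buf * cl[1] / (cl[1] + sp$km_nhe3) -
         sp$beta_nhe3 * cc[1] / (cc[1] + sp$km_nhe3))
    ja[1] <- ja[1] + jnhe3
  }
  if (sp$v_sglt > 0) {
    # electrogenic carrier: the apical potential biases the reverse
    # occupancy by the Boltzmann factor of the n translocated Na+ charges
    n <- sp$sglt_n
    occ_l <- cl[5] / (cl[5] + sp$km_sg) * (cl[1] / (cl[1] + sp$km_sna))^n
    occ_c <- cc[5] / (cc[5] + sp$km_sg) * (cc[1] / (cc[1] + sp$km_sna))^n
    ev <- exp(-n * min(max(va, -160), 160) / 26.7)
    jsglt <- tq * sp$v_sglt * (1 - sp$sglt_inh) * (occ_l - occ_c * ev)
    ja[5] <- ja[5] + jsglt
    ja[1] <- ja[1] + n * jsglt
  }
  if (sp$v_nkcc2 > 0) {
    ol <- cl[1] / (cl[1] + sp$km_nk_na) * cl[2] / (cl[2] + sp$km_nk_k) *
      (cl[3] / (cl[3] + sp$km_nk_cl))^2
    oc <- cc[1] / (cc[1] + sp$km_nk_na) * cc[2] / (cc[2] + sp$km_nk_k) *
      (cc[3] / (cc[3] + sp$km_nk_cl))^2
    jnk <- sp$v_nkcc2 * (ol - oc)
    ja[1] <- ja[1] + jnk; ja[2] <- ja[2] + jnk; ja[3] <- ja[3] + 2 * jnk
  }
  if (sp$v_ncc > 0) {
    ol <- cl[1] / (cl[1] + sp$km_ncc_na) * cl[3] / (cl[3] + sp$km_ncc_cl)
    oc <- cc[1] / (cc[1] + sp$km_ncc_na) * cc[3] / (cc[3] + sp$km_ncc_cl)
    jncc <- sp$v_ncc * (ol - oc)
    ja[1] <- ja[1] + jncc; ja[3] <- ja[3] + jncc
  }
  if (sp$p_enac > 0) ja[1] <- ja[1] + .ghk(1, cl[1], cc[1], va, sp$p_enac)
  if (sp$p_kap > 0) ja[2] <- ja[2] + .ghk(1, cl[2], cc[2], va, sp$p_kap)
  ja[4] <- ja[4] + (sp$p_urea_ap) * (cl[4] - cc[4])
  # small background permeability keeps every balance equation regular
  pb <- sp$p_bg
  ja[1] <- ja[1] + .ghk(1, cl[1], cc[1], va, pb)
  ja[2] <- ja[2] + .ghk(1, cl[2], cc[2], va, pb)
  ja[3] <- ja[3] + .ghk(-1, cl[3], cc[3], va, pb)
  ja[4] <- ja[4] + pb * (cl[4] - cc[4])
  ja[5] <- ja[5] + pb * (cl[5] - cc[5])

  # --- basolateral ---
  if (sp$v_pump > 0) {
    pump_cycle <- pumpfac * tq * sp$v_pump *
      (cc[1] / (cc[1] + sp$km_pump))^3
    jb[1] <- jb[1] + 3 * pump_cycle
    jb[2] <- jb[2] - 2 * pump_cycle
  }
  if (sp$v_kcl > 0) {
    oc <- cc[2] / (cc[2] + sp$km_kcl_k) * cc[3] / (cc[3] + sp$km_kcl_cl)
    os <- cs[2] / (cs[2] + sp$km_kcl_k) * cs[3] / (cs[3] + sp$km_kcl_cl)
    jk <- sp$v_kcl * (oc - os)
    jb[2] <- jb[2] + jk; jb[3] <- jb[3] + jk
  }
  if (sp$v_glut > 0) {
    jb[5] <- jb[5] + tq * sp$v_glut *
      (cc[5] / (cc[5] + sp$km_glut) - cs[5] / (cs[5] + sp$km_glut))
  }
  jb[1] <- jb[1] + .ghk(1, cc[1], cs[1], vb, sp$p_nabl + pb)
  jb[2] <- jb[2] + .ghk(1, cc[2], cs[2], vb, sp$p_kbl + pb)
  jb[3] <- jb[3] + .ghk(-1, cc[3], cs[3], vb, sp$p_clbl + pb)
  jb[4] <- jb[4] + (sp$p_urea_bl + pb) * (cc[4] - cs[4])
  jb[5] <- jb[5] + pb * (cc[5] - cs[5])

  # --- paracellular (lumen -> interstitium) ---
  jp <- numeric(6)
  for (i in 1:6) {
    drag <- (1 - sp$sigma[i]) * jv_p * .logmean(cl[i], cs[i])
    jp[i] <- drag + .ghk(sp$z[i], cl[i], cs[i], vt, sp$p_para[i])
  }

  if (want_flux) {
    return(list(ja = ja, jb = jb, jp = jp, jv_trans = jv_t, jv_para = jv_p,
                pump_cycle = pump_cycle, sglt_glucose = jsglt,
                jnhe3 = jnhe3, v_cell = vc, v_te = vt))
  }
  r <- numeric(7)
  r[1:5] <- ja - jb
  r[6] <- cc[1] + cc[2] - cc[3] - sp$a_imp
  # Open circuit: net current into the lumen vanishes. The NHE3 Na+ flux
  # is excluded (its secreted proton consumes one luminal buffer-anion
  # equivalent, so the pair is electroneutral); the buffer anion itself
  # enters only through its paracellular term.
  r[7] <- (ja[1] - jnhe3 + jp[1]) + (ja[2] + jp[2]) - (ja[3] + jp[3]) - jp[6]
  r
}

# Damped Newton with cached (chord) Jacobian for the cell system.
# cache: environment holding $J (7x7) reused across calls; pass fresh env
# to force recomputation.
cell_newton <- function(x0, cl, cs, sp, tq = 1, pumpfac = 1,
                        cache = new.env(), tol = 1e-10, max_iter = 60) {
  x <- x0
  fscale <- max(3 * sp$v_pump, sp$v_nhe3, 4 * sp$v_nkcc2, 2 * sp$v_ncc,
                100 * (sp$p_enac + sp$p_kap + sp$p_kbl + sp$p_clbl),
                1e-4)
  rscale <- c(rep(fscale, 5), 100, fscale)
  hstep <- c(rep(1e-6 * 30, 5), 1e-6 * 25, 1e-6 * 25)
  r <- cell_eval(x, cl, cs, sp, tq, pumpfac)
  best <- max(abs(r / rscale))
  if (!is.finite(best)) best <- Inf
  it <- 0
  chord_age <- if (is.null(cache$J)) Inf else cache$age
  for (it in seq_len(max_iter)) {
    if (best < tol) break
    if (is.infinite(chord_age) || chord_age > 25 || it > 6) {
      J <- matrix(0, 7, 7)
      for (j in 1:7) {
        xj <- x; xj[j] <- xj[j] + hstep[j]
        J[, j] <- (cell_eval(xj, cl, cs, sp, tq, pumpfac) - r) / hstep[j]
      }
      cache$J <- J
      cache$age <- 0
      chord_age <- 0
    }
    dx <- tryCatch(solve(cache$J, -r), error = function(e) NULL)
    if (is.null(dx)) { cache$J <- NULL; chord_age <- Inf; next }
    lam <- 1
    repeat {
      xn <- x + lam * dx
      xn[1:5] <- pmax(xn[1:5], 1e-9)
      rn <- cell_eval(xn, cl, cs, sp, tq, pumpfac)
      nn <- max(abs(rn / rscale))
      if (!is.finite(nn)) nn <- Inf
      if (nn < best * (1 - 1e-4 * lam) || nn < tol || lam < 1 / 64) break
      lam <- lam / 2
    }
    if (nn >= best && lam < 1 / 64 && chord_age > 0) {
      # stale Jacobian: force refresh and retry
      chord_age <- Inf
      next
    }
    x <- xn; r <- rn; best <- nn
    chord_age <- chord_age + 1
    cache$age <- chord_age
  }
  list(x = x, resid = best, converged = best < tol, iters = it)
}

#' Solve the epithelial cell compartment at one grid point
#'
#' Finds the steady state of the cell: cytosolic concentrations, cell
#' potential and transepithelial potential such that every solute's apical
#' influx equals its basolateral efflux, the cytosol is electroneutral
#' against the impermeant anion, and no net current crosses the epithelium.
#' Solved by damped Newton iteration.
#'
#' @param lumen Named luminal concentration vector (mM) over
#'   Na, K, Cl, urea, glucose.
#' @param interstitium Named interstitial concentration vector (mM).
#' @param segment Segment id (e.g. "PCT") or a compiled segment spec from
#'   [compile_segment()].
#' @param params A `nephro_params` list (ignored when `segment` is already
#'   compiled).
#' @param guess Optional initial state: list with `conc` (len 5), `v_cell`,
#'   `v_te`.
#' @param torque_multiplier Multiplier applied to transcellular
#'   transporters (flow/torque effect), default 1.
#' @return List of class `cell_state`: `conc` (named, mM), `v_cell`, `v_te`
#'   (mV), `fluxes` (apical/basolateral/paracellular breakdown),
#'   `residual`, `iterations`.
#' @export
#' @examples
#' p <- default_params()
#' cs <- solve_cell(p$plasma, p$plasma, "PCT", p)
#' cs$conc["Na"] < p$plasma["Na"]  # pump keeps cell Na low
solve_cell <- function(lumen, interstitium, segment = "PCT",
                       params = default_params(), guess = NULL,
                       torque_multiplier = 1) {
  sp <- if (is.list(segment)) segment else compile_segment(segment, params)
  if (!sp$has_cell)
    stop("segment ", sp$name, " has no cell compartment", call. = FALSE)
  fill_anion <- function(v) {
    out <- v[.ns_solutes]
    a <- if ("anion" %in% names(v)) unname(v["anion"]) else
      max(unname(out["Na"] + out["K"] - out["Cl"]), 1e-6)
    c(as.numeric(out), a)
  }
  cl <- fill_anion(lumen)
  cs <- fill_anion(interstitium)
  if (any(cl[1:5] <= 0) || any(cs[1:5] <= 0))
    stop("concentrations must be positive", call. = FALSE)
  x0 <- if (!is.null(guess)) {
    c(as.numeric(guess$conc[.ns_solutes]), guess$v_cell, guess$v_te)
  } else sp$cell0
  fit <- cell_newton(x0, cl, cs, sp)
  if (!fit$converged)
    stop(sprintf("cell solve failed to converge (segment %s, residual %.3g)",
                 sp$name, fit$resid), call. = FALSE)
  fl <- cell_eval(fit$x, cl, cs, sp, want_flux = TRUE)
  out <- list(conc = stats::setNames(fit$x[1:5], .ns_solutes),
              v_cell = fit$x[6], v_te = fit$x[7],
              impermeant_anion = sp$a_imp,
              fluxes = fl, residual = fit$resid, iterations = fit$iters)
  class(out) <- "cell_state"
  out
}
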