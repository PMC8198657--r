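test_that("every flux law vanishes at its equilibrium state", {
  act <- list(vmax = 1e-3, km_glucose = 2, km_na = 30)
  same <- list(na = 140, glucose = 5)
  expect_equal(unname(sglt_flux("SGLT2", same, same, act)[["glucose"]]), 0)
  expect_equal(unname(sglt_flux("SGLT1", same, same, act)[["glucose"]]), 0)
  expect_equal(glut_flux(5, 5, list(vmax = 1e-3, km = 10)), 0)
  conc <- c(Na = 140, K = 5, Cl = 113)
  a <- list(vmax = 1e-3, km = c(Na = 10, K = 5, Cl = 20))
  expect_equal(nkcc2_flux(conc, conc, a)$cycle, 0)
  expect_equal(ncc_flux(conc, conc, a)$cycle, 0)
  expect_equal(kcl_flux(conc, conc, a)$cycle, 0)
  # NHE3 equilibrium: forward occupancy balances the beta-biased reverse
  nh <- list(vmax = 1e-2, km = 30, beta = 0.5)
  # find lumen Na whose occupancy equals beta * occ(cell Na = 140)
  occ <- function(x) x / (x + 30)
  lum <- 30 * (0.5 * occ(140)) / (1 - 0.5 * occ(140))
  expect_equal(nhe3_flux(lum, 140, nh), 0, tolerance = 1e-15)
  expect_equal(channel_flux_ghk(1, 100, 100, 0, 1e-4), 0)
  # Nernst equilibrium: V = RT/F * ln(c_cis/c_trans) for z = +1
  v <- 26.7 * log(140 / 14)
  expect_equal(channel_flux_ghk(1, 140, 14, -v, 1e-4), 0, tolerance = 1e-12)
  expect_equal(water_flux(rep(100, 3), rep(100, 3), pf = 1), 0)
  expect_equal(paracellular_flux(1, 100, 100, 0, 0, 1e-5, 0.5), 0)
})

test_that("GHK reduces to Fick's law as the potential vanishes", {
  set.seed(7)
  for (i in 1:25) {
    c1 <- runif(1, 1, 300); c2 <- runif(1, 1, 300)
    p <- 10^runif(1, -6, -3)
    z <- sample(c(-1, 1), 1)
    fick <- p * (c1 - c2)
    g <- channel_flux_ghk(z, c1, c2, 1e-6, p)
    expect_lt(abs(g - fick) / max(abs(fick), 1e-12), 1e-6)
    # neutral solutes ignore the potential entirely
    expect_equal(channel_flux_ghk(0, c1, c2, runif(1, -80, 80), p), fick)
  }
})

test_that("carriers saturate at vmax and scale linearly with vmax", {
  act <- list(vmax = 2e-3, km_glucose = 2, km_na = 30)
  sat <- sglt_flux("SGLT2", list(na = 1e6, glucose = 1e6),
                   list(na = 1, glucose = 1e-9), act)
  expect_equal(unname(sat[["glucose"]]), 2e-3, tolerance = 1e-3)
  expect_equal(glut_flux(1e7, 0, list(vmax = 5e-4, km = 10)), 5e-4,
               tolerance = 1e-5)
  # flux is exactly proportional to vmax at fixed concentrations
  lum <- list(na = 140, glucose = 5); cell <- list(na = 20, glucose = 2)
  j1 <- sglt_flux("SGLT2", lum, cell, act, va_mV = 60)
  act2 <- act; act2$vmax <- 2 * act$vmax
  j2 <- sglt_flux("SGLT2", lum, cell, act2, va_mV = 60)
  expect_equal(unname(j2[["glucose"]]), 2 * unname(j1[["glucose"]]),
               tolerance = 1e-14)
  conc_l <- c(Na = 140, K = 5, Cl = 113); conc_c <- c(Na = 15, K = 130, Cl = 15)
  a <- list(vmax = 1e-3, km = c(Na = 10, K = 5, Cl = 20))
  a2 <- a; a2$vmax <- 2e-3
  expect_equal(nkcc2_flux(conc_l, conc_c, a2)$cycle,
               2 * nkcc2_flux(conc_l, conc_c, a)$cycle, tolerance = 1e-14)
})

test_that("SGLT inhibition scaling is exactly linear in 1 - fraction", {
  lum <- list(na = 140, glucose = 8.6); cell <- list(na = 18, glucose = 4)
  act0 <- list(vmax = 3e-3, km_glucose = 2, km_na = 30,
               inhibition_fraction = 0)
  j0 <- sglt_flux("SGLT2", lum, cell, act0, va_mV = 55)
  for (f in c(0.25, 0.5, 0.9, 1)) {
    actf <- act0; actf$inhibition_fraction <- f
    jf <- sglt_flux("SGLT2", lum, cell, actf, va_mV = 55)
    expect_equal(unname(jf[["glucose"]]), (1 - f) * unname(j0[["glucose"]]),
                 tolerance = 1e-14)
  }
})

test_that("coupled transporters keep their stoichiometry at every state", {
  set.seed(11)
  for (i in 1:20) {
    cis <- c(Na = runif(1, 5, 300), K = runif(1, 1, 150),
             Cl = runif(1, 5, 300))
    trans <- c(Na = runif(1, 5, 300), K = runif(1, 1, 150),
               Cl = runif(1, 5, 300))
    a <- list(vmax = 10^runif(1, -4, -2), km = c(Na = 10, K = 5, Cl = 20))
    nk <- nkcc2_flux(cis, trans, a)
    expect_equal(unname(nk$fluxes[["Na"]]), nk$cycle)
    expect_equal(unname(nk$fluxes[["K"]]), nk$cycle)
    expect_equal(unname(nk$fluxes[["Cl"]]), 2 * nk$cycle)
    # electroneutral: net charge per cycle is zero
    expect_equal(sum(c(1, 1, -1) * nk$fluxes[c("Na", "K", "Cl")]), 0,
                 tolerance = 1e-18)
    sg <- sglt_flux("SGLT1", list(na = cis[["Na"]], glucose = 5),
                    list(na = trans[["Na"]], glucose = 1),
                    list(vmax = 1e-3, km_glucose = 0.5, km_na = 30))
    expect_equal(unname(sg[["na"]]), 2 * unname(sg[["glucose"]]))
  }
})

test_that("Na/K-ATPase keeps 3:2 stoichiometry and saturates", {
  act <- list(vmax = 1e-2, km = 20)
  for (na in c(1, 5, 20, 100, 1e5)) {
    p <- nak_atpase_flux(na, act)
    expect_equal(p$na_efflux / p$k_influx, 1.5)
    expect_equal(p$na_efflux, 3 * p$cycle)
  }
  expect_lt(nak_atpase_flux(1e-9, act)$cycle, 1e-12)
  expect_equal(nak_atpase_flux(1e7, act)$cycle, 1e-2, tolerance = 1e-5)
})

test_that("GLUT flux is odd under swapping the two sides", {
  set.seed(3)
  for (i in 1:15) {
    a <- runif(1, 0, 30); b <- runif(1, 0, 30)
    act <- list(vmax = 1e-3, km = runif(1, 2, 20))
    expect_equal(glut_flux(a, b, act), -glut_flux(b, a, act),
                 tolerance = 1e-16)
  }
})

test_that("water flux is linear in Pf and zero when Pf = 0", {
  cl <- c(100, 5, 90); cb <- c(140, 5, 113)
  expect_equal(water_flux(cl, cb, pf = 0), 0)
  j1 <- water_flux(cl, cb, pf = 0.5)
  expect_equal(water_flux(cl, cb, pf = 1), 2 * j1, tolerance = 1e-14)
  expect_gt(j1, 0)  # hypotonic lumen -> reabsorption
})

test_that("torque multiplier behaves at reference, off, and clamps", {
  expect_equal(torque_scaling(1, 1, 1, 1, c_t = 1.3), 1)
  expect_gt(torque_scaling(1.5, 1, 1, 1, c_t = 1.3), 1)
  expect_lt(torque_scaling(0.6, 1, 1, 1, c_t = 1.3), 1)
  expect_equal(torque_scaling(5, 1, 1, 1, c_t = 0), 1)
  expect_equal(torque_scaling(100, 1, 1, 1, c_t = 1.3), 3)   # upper clamp
  expect_equal(torque_scaling(1e-6, 1, 1, 1, c_t = 1.3), 0.2) # lower clamp
  # torque falls with the square of the radius
  m_wide <- torque_scaling(1, 1, 2, 1, c_t = 1)
  expect_equal(m_wide, 1 + (0.25 - 1))
  expect_error(torque_scaling(-1, 1, 1, 1, 1), "positive")
})

test_that("paracellular flux reproduces the printed transport directions", {
  # higher luminal than interstitial glucose -> reabsorptive (positive)
  expect_gt(paracellular_flux(0, 20, 8.6, 0, 0, 1e-6, 0.95), 0)
  # luminal Na below interstitial with no drag -> secretory (negative)
  expect_lt(paracellular_flux(1, 120, 140, 0, 0, 1e-5, 0.75), 0)
  # solvent drag can reverse it
  expect_gt(paracellular_flux(1, 120, 140, 0, 1e-3, 1e-7, 0), 0)
})

test_that("the cell solver's internal fluxes match the exported laws", {
  p <- default_params()
  sp <- compile_segment("PCT", p)
  cs <- solve_cell(p$plasma, p$plasma, sp, p)
  va <- cs$v_te - cs$v_cell
  act <- list(vmax = sp$v_sglt, km_glucose = sp$km_sg, km_na = sp$km_sna)
  jg <- sglt_flux("SGLT2",
                  list(na = p$plasma[["Na"]], glucose = p$plasma[["glucose"]]),
                  list(na = cs$conc[["Na"]], glucose = cs$conc[["glucose"]]),
                  act, va_mV = va)
  expect_equal(cs$fluxes$sglt_glucose, unname(jg[["glucose"]]),
               tolerance = 1e-12)
  pump <- nak_atpase_flux(cs$conc[["Na"]],
                          list(vmax = sp$v_pump, km = sp$km_pump))
  expect_equal(cs$fluxes$pump_cycle, pump$cycle, tolerance = 1e-12)
})
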