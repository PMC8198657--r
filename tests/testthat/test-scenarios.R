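test_that("the diabetes scenarios encode the prescribed parameter changes", {
  m <- moderate_diabetes()
  expect_equal(m$plasma_glucose, 8.6)
  expect_equal(unname(m$sngfr_multiplier), c(1.27, 1.10))
  expect_equal(unname(m$proximal_geometry), c(1.10, 1.10))
  expect_equal(m$distal_diameter, 1.18)
  expect_equal(m$distal_length, 1.07)
  tm <- m$transporter_multipliers
  fac <- function(tr) unlist(lapply(tm, function(r)
    if (r$transporter == tr) r$factor))
  expect_equal(fac("SGLT2"), 1.38)
  expect_equal(fac("GLUT2"), 1.50)
  expect_equal(fac("SGLT1"), 0.67)
  expect_equal(fac("NKCC2"), 1.10)
  expect_equal(sort(fac("NaKATPase")), c(1.10, 1.20))
  expect_equal(unname(m$water_pf), c(1.55, 1.40))
  expect_equal(m$pump_axial$IMCD$breaks, c(2 / 3, 1))
  expect_equal(m$pump_axial$IMCD$factors, c(1.5, 2.5))

  s <- severe_diabetes()
  expect_equal(s$plasma_glucose, 20)
  expect_equal(unname(s$proximal_geometry), c(1.28, 1.28))
  expect_equal(s$distal_diameter, 1.42)
  expect_equal(s$pump_axial$IMCD$factors, 2.5)
})

test_that("scenario application is declarative and reproducible", {
  p <- default_params()
  arch <- build_default_architecture()
  c1 <- apply_scenario(p, arch, moderate_diabetes())
  c2 <- apply_scenario(p, arch, moderate_diabetes())
  expect_identical(c1$params, c2$params)
  expect_identical(c1$arch, c2$arch)
  # inputs unchanged
  expect_equal(p$plasma[["glucose"]], 5)
  expect_equal(arch$nephron_classes$sngfr_nl_min[1], 100)
  # multipliers landed where prescribed
  expect_equal(get_param(c1$params, "segments.PCT.apical.sglt.vmax"),
               1.38 * get_param(p, "segments.PCT.apical.sglt.vmax"))
  expect_equal(get_param(c1$params, "segments.S3.apical.sglt.vmax"),
               0.67 * get_param(p, "segments.S3.apical.sglt.vmax"))
  expect_equal(get_param(c1$params, "segments.mTAL.basolateral.pump.vmax"),
               1.20 * get_param(p, "segments.mTAL.basolateral.pump.vmax"))
  expect_equal(get_param(c1$params, "segments.CNT.basolateral.pump.vmax"),
               1.10 * get_param(p, "segments.CNT.basolateral.pump.vmax"))
  expect_equal(get_param(c1$params, "segments.CCD.pf_trans"),
               1.55 * get_param(p, "segments.CCD.pf_trans"))
  expect_equal(get_param(c1$params, "segments.IMCD.pf_trans"),
               1.40 * get_param(p, "segments.IMCD.pf_trans"))
  # proximal hypertrophy
  g0 <- arch$segments$superficial
  g1 <- c1$arch$segments$superficial
  expect_equal(g1$inner_diameter_cm[g1$segment_id == "PCT"],
               1.10 * g0$inner_diameter_cm[g0$segment_id == "PCT"])
  expect_equal(g1$length_cm[g1$segment_id == "CNT"],
               1.07 * g0$length_cm[g0$segment_id == "CNT"])
  expect_equal(g1$inner_diameter_cm[g1$segment_id == "DCT"],
               1.18 * g0$inner_diameter_cm[g0$segment_id == "DCT"])
})

test_that("severe diabetes raises GFR by the population-weighted factor", {
  arch <- build_default_architecture()
  ctx <- apply_scenario(default_params(), arch, severe_diabetes())
  ratio <- single_kidney_gfr(ctx$arch)$l_day / single_kidney_gfr(arch)$l_day
  expected <- (0.85 * 1.27 * 100 + 0.15 * 1.10 * 133) /
    (0.85 * 100 + 0.15 * 133)
  expect_equal(ratio, expected, tolerance = 1e-12)
  expect_equal(ratio, 1.24, tolerance = 0.005)
})

test_that("SGLT2 inhibition changes only inhibition and hemodynamics", {
  nd <- nondiabetic()
  ndi <- with_sglt2i(nd)
  expect_equal(ndi$sglt2_inhibition_fraction, 0.9)
  expect_equal(unname(ndi$sngfr_multiplier),
               0.97 * unname(nd$sngfr_multiplier))
  same <- setdiff(names(nd), c("name", "sngfr_multiplier",
                               "sglt2_inhibition_fraction",
                               "gfr_override_l_day"))
  expect_identical(nd[same], ndi[same])

  sev <- severe_diabetes()
  sevi <- with_sglt2i(sev)
  expect_equal(sevi$gfr_override_l_day, 151.2)
  expect_equal(sevi$plasma_glucose, 20)  # acute: plasma unchanged
  expect_identical(sev[setdiff(names(sev),
                               c("name", "sglt2_inhibition_fraction",
                                 "gfr_override_l_day"))],
                   sevi[setdiff(names(sevi),
                                c("name", "sglt2_inhibition_fraction",
                                  "gfr_override_l_day"))])
  # the override lands exactly on the non-diabetic whole-kidney GFR
  ctx <- apply_scenario(default_params(), build_default_architecture(), sevi)
  expect_equal(single_kidney_gfr(ctx$arch)$l_day, 151.2, tolerance = 1e-10)
})

test_that("the results-text GFR mode rescales moderate diabetes to +10%", {
  arch <- build_default_architecture()
  ctx <- apply_scenario(default_params(), arch,
                        moderate_diabetes(gfr_mode = "results_text"))
  expect_equal(single_kidney_gfr(ctx$arch)$l_day,
               1.10 * single_kidney_gfr(arch)$l_day, tolerance = 1e-10)
})

test_that("run configurations validate before solving", {
  expect_error(run_config("bogus"), "unknown scenario")
  expect_error(run_config("nd", params_file = "no/such/file.yaml"),
               "not found")
  expect_error(run_config("nd", grid_mult = 0), "positive")
  cfg <- run_config("dm_sev", sglt2i = TRUE)
  expect_s3_class(cfg, "run_config")
})
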