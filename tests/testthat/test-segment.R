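test_that("an inert tube passes its inlet through unchanged", {
  p <- silence_segment(default_params(), "SDL")
  sp <- compile_segment("SDL", p)
  inlet <- list(flow = 100 * 1e-6 / 60, conc = p$plasma, pressure = 13)
  sol <- solve_segment(inlet, sp)
  expect_equal(sol$outlet$flow, inlet$flow, tolerance = 1e-14)
  expect_equal(unname(sol$outlet$conc[names(p$plasma)]),
               unname(p$plasma), tolerance = 1e-12)
  expect_equal(unname(sol$reab), rep(0, 6))
  expect_equal(sol$water_reab, 0)
})

test_that("inert transport is exactly linear in the inlet flow", {
  p <- silence_segment(default_params(), "LDL")
  sp <- compile_segment("LDL", p, length_cm = 0.4)
  i1 <- list(flow = 50 * 1e-6 / 60, conc = p$plasma, pressure = 13)
  i2 <- list(flow = 100 * 1e-6 / 60, conc = p$plasma, pressure = 13)
  s1 <- solve_segment(i1, sp)
  s2 <- solve_segment(i2, sp)
  expect_equal(s2$outlet$flow, 2 * s1$outlet$flow, tolerance = 1e-12)
  expect_equal(unname(s2$outlet$conc), unname(s1$outlet$conc),
               tolerance = 1e-12)
})

test_that("segment reabsorption equals inlet minus outlet exactly", {
  p <- default_params()
  sp <- compile_segment("PCT", p)
  inlet <- list(flow = 100 * 1e-6 / 60, conc = p$plasma, pressure = 13)
  sol <- solve_segment(inlet, sp)
  inflow <- inlet$flow * as.numeric(p$plasma)
  outflow <- sol$outlet$flow * as.numeric(sol$outlet$conc)
  expect_equal(unname(inflow - outflow), unname(sol$reab),
               tolerance = 1e-12)
  expect_equal(inlet$flow - sol$outlet$flow, sol$water_reab,
               tolerance = 1e-14)
  # transcellular + paracellular components recompose the total closely
  expect_equal(unname(sol$reab_trans + sol$reab_para), unname(sol$reab),
               tolerance = 1e-6 * max(abs(sol$reab)))
})

test_that("the proximal tubule reabsorbs the majority of water, Na and glucose", {
  p <- default_params()
  inlet <- list(flow = 100 * 1e-6 / 60, conc = p$plasma, pressure = 13)
  pct <- solve_segment(inlet, compile_segment("PCT", p))
  s3 <- solve_segment(pct$outlet, compile_segment("S3", p),
                      cell_guess = pct$cell_exit)
  fna <- inlet$flow * p$plasma[["Na"]]
  fw <- inlet$flow
  fg <- inlet$flow * p$plasma[["glucose"]]
  expect_gt((pct$reab[["Na"]] + s3$reab[["Na"]]) / fna, 0.5)
  expect_gt((pct$water_reab + s3$water_reab) / fw, 0.5)
  expect_gt(pct$reab[["glucose"]] / fg, 0.9)
  # near-isotonic: water and Na fractions track within 15 points
  expect_lt(abs((pct$reab[["Na"]] / fna) - pct$water_reab / fw), 0.15)
})

test_that("halving the grid spacing changes segment reabsorption < 0.1%", {
  p <- default_params()
  inlet <- list(flow = 100 * 1e-6 / 60, conc = p$plasma, pressure = 13)
  a <- solve_segment(inlet, compile_segment("PCT", p, grid_points = 40))
  b <- solve_segment(inlet, compile_segment("PCT", p, grid_points = 80))
  for (s in c("Na", "Cl", "glucose"))
    expect_lt(abs(a$reab[[s]] - b$reab[[s]]) / abs(b$reab[[s]]), 1e-3)
  expect_lt(abs(a$water_reab - b$water_reab) / b$water_reab, 1e-3)
})

test_that("a segment that would run dry raises a diagnostic error", {
  p <- default_params()
  sp <- compile_segment("PCT", p)
  inlet <- list(flow = 0.5 * 1e-6 / 60, conc = p$plasma, pressure = 13)
  expect_error(solve_segment(inlet, sp), "runs dry|failed")
  expect_error(solve_segment(list(flow = 0, conc = p$plasma), sp),
               "positive")
})

test_that("solver output is deterministic across repeated runs", {
  p <- default_params()
  sp <- compile_segment("mTAL", p)
  inlet <- list(flow = 20 * 1e-6 / 60,
                conc = c(Na = 270, K = 10, Cl = 280, urea = 28,
                         glucose = 0.5, anion = 3),
                pressure = 10)
  a <- solve_segment(inlet, sp)
  b <- solve_segment(inlet, sp)
  expect_identical(a$conc, b$conc)
  expect_identical(a$reab, b$reab)
})
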