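test_that("filtered loads reproduce the GFR x plasma arithmetic", {
  # non-diabetic: 151.13 L/day x 5 mM glucose
  arch <- build_default_architecture()
  gfr <- single_kidney_gfr(arch)$l_day
  expect_equal(filtered_load(nondiabetic(), "glucose"), gfr * 5 / 1000,
               tolerance = 1e-12)
  # moderate diabetes + SGLT2i: the GFR override makes this exactly
  # 151.2 L/day x 8.6 mM = 1.30 mol/day
  expect_equal(filtered_load(with_sglt2i(moderate_diabetes()), "glucose"),
               151.2 * 8.6 / 1000, tolerance = 1e-10)
  # a solute with zero plasma concentration filters nothing
  sc <- nondiabetic()
  sc$plasma_glucose <- 0
  expect_equal(filtered_load(sc, "glucose"), 0)
})

test_that("whole-kidney reports close their mass balance", {
  r <- scenario_report("nd")
  expect_lt(max(abs(r$conservation)), 1e-5)
  # fractional excretions of reabsorbed solutes within [0, 1]
  for (s in c("Na", "Cl", "glucose", "urea"))
    expect_true(r$fractional_excretion[[s]] >= 0 &&
                  r$fractional_excretion[[s]] <= 1)
  expect_gte(r$fractional_excretion[["K"]], 0)
  # active + passive recompose the total exactly
  expect_equal(r$tna$active + r$tna$passive, r$tna$total, tolerance = 1e-12)
  expect_equal(tna_split(r)$total, r$tna$total)
  # macula densa values exist for all six classes
  expect_length(r$md_cl_mM, 6)
  expect_true(all(r$md_cl_mM > 0))
})

test_that("normalizing a report by itself is identically one", {
  r <- scenario_report("nd")
  n <- normalize_report(r, r)
  expect_equal(unname(n$filtered), rep(1, 6))
  expect_equal(n$urine_volume, 1)
  expect_equal(n$gfr, 1)
  expect_equal(n$tna_total, 1)
  seg <- n$segmental[is.finite(n$segmental)]
  expect_true(all(abs(seg[!is.na(seg)] - 1) < 1e-12))
})

test_that("normalization flags a zero reference as undefined", {
  r <- scenario_report("nd")
  ref <- r
  ref$excretion_mmol_day["glucose"] <- 0
  n <- normalize_report(r, ref)
  expect_true(is.na(n$excretion[["glucose"]]))
  expect_false(anyNA(n$excretion[c("Na", "K", "Cl")]))
})

test_that("figure tables are written with the expected shape", {
  reps <- list(nd = scenario_report("nd"), sev = scenario_report("sev"))
  d <- tempfile("figtab")
  paths <- figure_tables(reps, d, ref = "nd")
  expect_true(all(file.exists(file.path(
    d, c("glucose_handling.csv", "transport.csv", "segmental.csv",
         "normalized.csv")))))
  glu <- read.csv(file.path(d, "glucose_handling.csv"))
  expect_equal(nrow(glu), 2)
  expect_true(all(c("filtered_mol_day", "excretion_mol_day", "fe_pct",
                    "pct_reab_pct", "s3_reab_pct") %in% names(glu)))
  seg <- read.csv(file.path(d, "segmental.csv"))
  expect_true(all(c("PCT", "mTAL", "IMCD") %in% seg$segment))
  expect_error(figure_tables(list(), d), "no reports")
  unlink(d, recursive = TRUE)
})

test_that("profiles export as a tidy table covering every segment", {
  p <- default_params()
  ctx <- apply_scenario(p, build_default_architecture(), nondiabetic())
  sol <- solve_nephron("superficial", ctx, stop_after = "S3")
  fake <- list(classes = list(superficial = sol), cd = list(),
               ctx = ctx, counts = c(superficial = 850000))
  class(fake) <- "kidney_solution"
  df <- profiles_df(fake)
  expect_true(all(c("PCT", "S3") %in% df$segment))
  expect_true(all(c("c_Na_mM", "c_glucose_mM", "c_anion_mM") %in% names(df)))
  expect_true(all(diff(df$x_cm[df$segment == "PCT"]) > 0))
  expect_true(all(df$Fv_nl_min > 0))
})
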