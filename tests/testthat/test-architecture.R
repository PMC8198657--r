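test_that("default architecture has six classes with an 85/15 split", {
  arch <- build_default_architecture()
  cls <- arch$nephron_classes
  expect_equal(nrow(cls), 6)
  expect_equal(cls$population_fraction[cls$id == "superficial"], 0.85)
  expect_equal(sum(cls$population_fraction), 1, tolerance = 1e-14)
  expect_equal(sum(cls$population_fraction[grepl("^jm", cls$id)]), 0.15,
               tolerance = 1e-14)
  expect_true(all(cls$sngfr_nl_min > 0))
  expect_equal(arch$total_nephrons, 1e6)
  # loop turn depths staggered, deepest reaching the papillary tip
  jm <- cls[grepl("^jm", cls$id), ]
  expect_true(all(diff(jm$loop_turn_depth_mm) > 0))
  expect_equal(max(jm$loop_turn_depth_mm) / 10, arch$im_depth_cm)
  # population decreases with depth (most long loops turn high)
  expect_true(all(diff(jm$population_fraction) < 0))
})

test_that("single-kidney GFR reproduces the population-weighted arithmetic", {
  arch <- build_default_architecture()
  g <- single_kidney_gfr(arch)
  expect_equal(g$ml_min, 0.85 * 100 + 0.15 * 133, tolerance = 1e-12)
  expect_equal(g$l_day, g$ml_min * 1.44, tolerance = 1e-12)
  # exactly linear in SNGFR and in nephron count
  a2 <- arch
  a2$nephron_classes$sngfr_nl_min <- 3 * a2$nephron_classes$sngfr_nl_min
  expect_equal(single_kidney_gfr(a2)$ml_min, 3 * g$ml_min, tolerance = 1e-12)
  a3 <- arch
  a3$total_nephrons <- arch$total_nephrons / 4
  expect_equal(single_kidney_gfr(a3)$ml_min, g$ml_min / 4, tolerance = 1e-12)
  a4 <- arch
  a4$nephron_classes$sngfr_nl_min <- 0
  expect_equal(single_kidney_gfr(a4)$ml_min, 0)
})

test_that("geometry scaling is selective, multiplicative and commutes", {
  arch <- build_default_architecture()
  a <- scale_geometry(arch, "proximal", 1.10, 1.10)
  g0 <- arch$segments$superficial
  g1 <- a$segments$superficial
  prox <- g0$segment_id %in% c("PCT", "S3")
  expect_equal(g1$inner_diameter_cm[prox], 1.10 * g0$inner_diameter_cm[prox])
  expect_equal(g1$length_cm[prox], 1.10 * g0$length_cm[prox])
  expect_equal(g1$inner_diameter_cm[!prox], g0$inner_diameter_cm[!prox])
  # original untouched
  expect_equal(arch$segments$superficial, g0)
  # identity
  expect_equal(scale_geometry(arch, "distal", 1, 1), arch)
  # commutes: a then b equals a*b in one step
  ab <- scale_geometry(scale_geometry(arch, "distal", 1.18, 1.07),
                       "distal", 1.2, 1.1)
  once <- scale_geometry(arch, "distal", 1.18 * 1.2, 1.07 * 1.1)
  expect_equal(ab$segments$jm3, once$segments$jm3, tolerance = 1e-14)
  expect_error(scale_geometry(arch, "proximal", -1, 1), "positive")
  expect_error(scale_geometry(arch, c("PCT", "bogus"), 1.1, 1), "unknown")
})

test_that("coalescence merges conserve water and solute flows", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    flows <- runif(k, 1e-8, 1e-6)
    concs <- matrix(runif(k * 6, 1, 300), k, 6)
    w <- sample(1:200000, k)
    m <- merge_streams(flows, concs, w)
    expect_equal(m$flow, sum(w * flows), tolerance = 1e-14)
    in_solute <- colSums(concs * (w * flows))
    out_solute <- m$flow * m$conc
    expect_lt(max(abs(out_solute - in_solute) / in_solute), 1e-10)
  }
})

test_that("architecture serializes to YAML and back unchanged", {
  arch <- build_default_architecture()
  f <- tempfile(fileext = ".yaml")
  write_architecture(arch, f)
  back <- read_architecture(f)
  expect_equal(back$nephron_classes, arch$nephron_classes)
  expect_equal(back$segments$superficial, arch$segments$superficial)
  expect_equal(back$topology$cnt_merge_ratio, 10)
  expect_equal(back$total_nephrons, 1e6)
  unlink(f)
})
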