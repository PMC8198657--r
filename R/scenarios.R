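# Declarative scenario overlays: plasma composition, hemodynamics,
# hypertrophy, transporter regulation and SGLT2 inhibition.

new_scenario <- function(name, plasma_glucose = 5,
                         sngfr_multiplier = c(superficial = 1, jm = 1),
                         proximal_geometry = c(diameter = 1, length = 1),
                         distal_diameter = 1, distal_length = 1,
                         transporter_multipliers = list(),
                         pump_axial = list(),
                         water_pf = c(CCD = 1, IMCD = 1),
                         sglt2_inhibition_fraction = 0,
                         gfr_override_l_day = NULL,
                         gfr_mode = "methods") {
  sc <- list(name = name, plasma_glucose = plasma_glucose,
             sngfr_multiplier = sngfr_multiplier,
             proximal_geometry = proximal_geometry,
             distal_diameter = distal_diameter,
             distal_length = distal_length,
             transporter_multipliers = transporter_multipliers,
             pump_axial = pump_axial,
             water_pf = water_pf,
             sglt2_inhibition_fraction = sglt2_inhibition_fraction,
             gfr_override_l_day = gfr_override_l_day,
             gfr_mode = gfr_mode)
  stopifnot(all(unlist(sc$sngfr_multiplier) > 0),
            sc$sglt2_inhibition_fraction >= 0,
            sc$sglt2_inhibition_fraction <= 1)
  class(sc) <- "scenario"
  sc
}

rule <- function(segments, transporter, factor)
  list(segments = segments, transporter = transporter, factor = factor)

#' Non-diabetic baseline scenario
#'
#' Identity overlay: plasma glucose 5 mM, all multipliers 1.
#'
#' @return A `scenario` object.
#' @export
nondiabetic <- function() new_scenario("nondiabetic")

diabetes_common_rules <- function() {
  all_but_tal_imcd <- c("PCT", "S3", "DCT", "CNT", "CCD", "OMCD")
  list(
    rule("PCT", "SGLT2", 1.38),
    rule("PCT", "GLUT2", 1.50),
    rule("S3", "SGLT1", 0.67),
    rule(c("mTAL", "cTAL"), "NKCC2", 1.10),
    rule(all_but_tal_imcd, "NaKATPase", 1.10),
    rule(c("mTAL", "cTAL"), "NaKATPase", 1.20)
  )
}

#' Moderate diabetes scenario
#'
#' Plasma glucose 8.6 mM; SNGFR x1.27 (superficial) and x1.10
#' (juxtamedullary); proximal diameter and length x1.10; distal diameter
#' x1.18 and length x1.07; SGLT2 x1.38, GLUT2 x1.50, NKCC2 x1.10,
#' SGLT1 x0.67; Na/K-ATPase x1.10 everywhere except the thick ascending
#' limbs (x1.20) and the IMCD (x1.50 over the initial two-thirds, x2.50
#' over the remainder); CCD water permeability x1.55, IMCD x1.40.
#'
#' @param gfr_mode `"methods"` keeps the per-class SNGFR increases;
#'   `"results_text"` rescales all SNGFRs to a +10% whole-kidney GFR.
#' @return A `scenario` object.
#' @export
moderate_diabetes <- function(gfr_mode = c("methods", "results_text")) {
  gfr_mode <- match.arg(gfr_mode)
  new_scenario("moderate_diabetes", plasma_glucose = 8.6,
               sngfr_multiplier = c(superficial = 1.27, jm = 1.10),
               proximal_geometry = c(diameter = 1.10, length = 1.10),
               distal_diameter = 1.18, distal_length = 1.07,
               transporter_multipliers = diabetes_common_rules(),
               pump_axial = list(IMCD = list(breaks = c(2 / 3, 1),
                                             factors = c(1.5, 2.5))),
               water_pf = c(CCD = 1.55, IMCD = 1.40),
               gfr_mode = gfr_mode)
}

#' Severe diabetes scenario
#'
#' As [moderate_diabetes()] but plasma glucose 20 mM, proximal diameter
#' and length x1.28, distal diameter x1.42 (length x1.07), and IMCD
#' Na/K-ATPase x2.50 along the entire segment.
#'
#' @inheritParams moderate_diabetes
#' @return A `scenario` object.
#' @export
severe_diabetes <- function(gfr_mode = c("methods", "results_text")) {
  gfr_mode <- match.arg(gfr_mode)
  new_scenario("severe_diabetes", plasma_glucose = 20,
               sngfr_multiplier = c(superficial = 1.27, jm = 1.10),
               proximal_geometry = c(diameter = 1.28, length = 1.28),
               distal_diameter = 1.42, distal_length = 1.07,
               transporter_multipliers = diabetes_common_rules(),
               pump_axial = list(IMCD = list(breaks = 1,
                                             factors = 2.5)),
               water_pf = c(CCD = 1.55, IMCD = 1.40),
               gfr_mode = gfr_mode)
}

#' Add acute SGLT2 inhibition to a scenario
#'
#' Sets the SGLT2 inhibition fraction to 0.9 (90% inhibition in all
#' nephrons). For the non-diabetic baseline the SNGFR of every nephron is
#' reduced by 3%; for a diabetic scenario the whole-kidney GFR is lowered
#' to its non-diabetic level of 151.2 L/day. Plasma glucose is unchanged
#' (acute administration). No other parameter is touched.
#'
#' @param base A `scenario` from [nondiabetic()], [moderate_diabetes()] or
#'   [severe_diabetes()].
#' @return A new `scenario` object.
#' @export
with_sglt2i <- function(base) {
  stopifnot(inherits(base, "scenario"))
  sc <- base
  sc$name <- paste0(base$name, "_sglt2i")
  sc$sglt2_inhibition_fraction <- 0.9
  if (base$name == "nondiabetic") {
    sc$sngfr_multiplier <- sc$sngfr_multiplier * 0.97
  } else {
    sc$gfr_override_l_day <- 151.2
  }
  sc
}

# Map a transporter id to the parameter path(s) it scales within one
# segment's parameter block.
transporter_paths <- function(transporter) {
  switch(transporter,
    SGLT2 = , SGLT1 = "apical.sglt.vmax",
    GLUT1 = , GLUT2 = "basolateral.glut.vmax",
    NHE3 = "apical.nhe3.vmax",
    NKCC = , NKCC2 = "apical.nkcc2.vmax",
    NCC = "apical.ncc.vmax",
    ENaC = "apical.enac",
    ROMK = "apical.p_k",
    NaKATPase = "basolateral.pump.vmax",
    KCl_cotransport = "basolateral.kcl.vmax",
    stop("unknown transporter id: ", transporter, call. = FALSE))
}

#' Apply a scenario to baseline parameters and architecture
#'
#' Purely declarative: returns a solve context containing the modified
#' parameter list and architecture; the inputs are unchanged, and applying
#' the same scenario twice to fresh baselines yields identical contexts.
#'
#' @param params A `nephro_params` list.
#' @param arch A `kidney_architecture`.
#' @param scenario A `scenario` object.
#' @param grid_mult Multiplier on grid points per segment (grid-refinement
#'   studies).
#' @return A list of class `solve_context` with elements `params`, `arch`,
#'   `scenario`, `sglt2_inhibition`, `pump_axial`, `grid_mult`.
#' @export
apply_scenario <- function(params, arch, scenario, grid_mult = 1) {
  stopifnot(inherits(scenario, "scenario"))
  p <- params
  a <- arch
  p$plasma["glucose"] <- scenario$plasma_glucose

  # hemodynamics
  m <- scenario$sngfr_multiplier
  sup <- a$nephron_classes$id == "superficial"
  a$nephron_classes$sngfr_nl_min[sup] <-
    a$nephron_classes$sngfr_nl_min[sup] * m[["superficial"]]
  a$nephron_classes$sngfr_nl_min[!sup] <-
    a$nephron_classes$sngfr_nl_min[!sup] * m[["jm"]]
  if (identical(scenario$gfr_mode, "results_text") &&
      scenario$name != "nondiabetic") {
    target <- single_kidney_gfr(arch)$l_day * 1.10
    fac <- target / single_kidney_gfr(a)$l_day
    a$nephron_classes$sngfr_nl_min <- a$nephron_classes$sngfr_nl_min * fac
  }
  if (!is.null(scenario$gfr_override_l_day)) {
    fac <- scenario$gfr_override_l_day / single_kidney_gfr(a)$l_day
    a$nephron_classes$sngfr_nl_min <- a$nephron_classes$sngfr_nl_min * fac
  }

  # hypertrophy
  pg <- scenario$proximal_geometry
  if (pg[["diameter"]] != 1 || pg[["length"]] != 1)
    a <- scale_geometry(a, "proximal", pg[["diameter"]], pg[["length"]])
  if (scenario$distal_diameter != 1)
    a <- scale_geometry(a, c("DCT", "CNT", "CCD", "OMCD", "IMCD"),
                        scenario$distal_diameter, 1)
  if (scenario$distal_length != 1)
    a <- scale_geometry(a, c("DCT", "CNT"), 1, scenario$distal_length)

  # transporter regulation
  for (r in scenario$transporter_multipliers) {
    path <- transporter_paths(r$transporter)
    for (seg in r$segments) {
      full <- paste0("segments.", seg, ".", path)
      cur <- tryCatch(get_param(p, full), error = function(e) NULL)
      if (!is.null(cur)) p <- set_param(p, full, cur * r$factor)
    }
  }
  # transcellular water permeability
  for (seg in names(scenario$water_pf)) {
    f <- scenario$water_pf[[seg]]
    if (f != 1)
      p <- set_param(p, paste0("segments.", seg, ".pf_trans"),
                     get_param(p, paste0("segments.", seg, ".pf_trans")) * f)
  }
  if (grid_mult != 1) {
    for (nm in names(a$segments))
      a$segments[[nm]]$grid_points <-
        as.integer(round(a$segments[[nm]]$grid_points * grid_mult))
  }
  ctx <- list(params = p, arch = a, scenario = scenario,
              sglt2_inhibition = scenario$sglt2_inhibition_fraction,
              pump_axial = scenario$pump_axial, grid_mult = grid_mult)
  class(ctx) <- "solve_context"
  ctx
}
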