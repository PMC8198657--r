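# Derived whole-kidney quantities: filtered loads, segmental transport,
# excretions, macula densa [Cl-], and the active/passive split of total
# Na+ transport.

#' Filtered load of a solute under a scenario
#'
#' Whole-kidney GFR (after scenario application, including any GFR
#' override) times the scenario plasma concentration.
#'
#' @param scenario A `scenario` object.
#' @param solute Solute name ("Na", "K", "Cl", "urea", "glucose").
#' @param params,arch Baseline parameters and architecture.
#' @return Filtered load in mol/day.
#' @export
#' @examples
#' filtered_load(nondiabetic(), "glucose")  # 151.2 L/day * 5 mM
filtered_load <- function(scenario, solute, params = default_params(),
                          arch = build_default_architecture()) {
  ctx <- apply_scenario(params, arch, scenario)
  gfr <- single_kidney_gfr(ctx$arch)$l_day
  unname(gfr * ctx$params$plasma[solute] / 1000)  # L/day * mmol/L -> mol/day
}

segment_order <- function() .ns_segment_ids

#' Build a whole-kidney report from a solved kidney
#'
#' Aggregates per-nephron segment solutions (population-scaled) and the
#' collecting duct into kidney totals: filtered loads, per-segment
#' per-solute reabsorption, urinary excretion, urine volume, fractional
#' excretions, macula densa [Cl-] per nephron class, and total/active/
#' passive Na+ transport.
#'
#' @param sol A `kidney_solution` from [solve_kidney()].
#' @return A `kidney_report` list; see Details.
#' @details Elements: `gfr_l_day`; `filtered_mmol_day`, `excretion_mmol_day`,
#'   `fractional_excretion` (named per solute); `urine_l_day`; `segmental`
#'   (segments x solutes matrix, mmol/day, kidney-scaled); `segmental_water`
#'   (L/day); `md_cl_mM` (per class); `tna` (total/active/passive,
#'   mmol/day); `glucose` (per-segment fractions of filtered glucose and
#'   SGLT-mediated shares); `conservation` (relative residual per solute).
#' @export
kidney_report <- function(sol) {
  stopifnot(inherits(sol, "kidney_solution"))
  ctx <- sol$ctx
  gfr <- single_kidney_gfr(ctx$arch)$l_day
  plasma <- ctx$params$plasma
  filtered <- gfr * plasma   # mmol/day
  excret <- sol$urine$excretion_mmol_day
  counts <- sol$counts

  segs <- segment_order()
  segmental <- matrix(0, length(segs), 6,
                      dimnames = list(segs, .ns_lum))
  seg_water <- stats::setNames(numeric(length(segs)), segs)
  seg_trans <- segmental
  seg_para <- segmental
  active_umol_s <- 0
  sglt_glu <- c(PCT = 0, S3 = 0)

  add_class <- function(s, w) {
    for (nm in names(s$segments)) {
      seg <- s$segments[[nm]]
      segmental[nm, ] <<- segmental[nm, ] + w * seg$reab * 86.4
      seg_trans[nm, ] <<- seg_trans[nm, ] + w * seg$reab_trans * 86.4
      seg_para[nm, ] <<- seg_para[nm, ] + w * seg$reab_para * 86.4
      seg_water[nm] <<- seg_water[nm] + w * seg$water_reab * 86.4
      active_umol_s <<- active_umol_s + w * 3 * seg$pump_cycles
      if (nm %in% names(sglt_glu))
        sglt_glu[nm] <<- sglt_glu[nm] + w * seg$sglt_glucose * 86.4
    }
  }
  for (nm in names(sol$classes)) add_class(sol$classes[[nm]], counts[nm])
  add_class(list(segments = sol$cd), 1)   # already kidney-scaled

  total_reab <- colSums(segmental)
  conservation <- (filtered - total_reab - excret) / pmax(filtered, 1e-9)

  tna_total <- filtered["Na"] - excret["Na"]
  tna_active <- active_umol_s * 86.4
  md_cl <- vapply(sol$classes, function(s)
    unname(s$segments$cTAL$outlet$conc["Cl"]), 0)

  fg <- filtered["glucose"]
  glucose <- list(
    filtered_mol_day = unname(fg) / 1000,
    excretion_mol_day = unname(excret["glucose"]) / 1000,
    fractional_excretion = unname(excret["glucose"] / fg),
    pct_fraction = unname(segmental["PCT", "glucose"] / fg),
    s3_fraction = unname(segmental["S3", "glucose"] / fg),
    sglt2_mediated_fraction = unname(sglt_glu["PCT"] / fg),
    sglt1_mediated_fraction = unname(sglt_glu["S3"] / fg),
    paracellular_proximal_fraction =
      unname((seg_para["PCT", "glucose"] + seg_para["S3", "glucose"]) / fg)
  )

  rep <- list(
    scenario = ctx$scenario$name,
    gfr_mode = ctx$scenario$gfr_mode,
    gfr_l_day = gfr,
    filtered_mmol_day = filtered,
    excretion_mmol_day = excret,
    fractional_excretion = excret / filtered,
    urine_l_day = sol$urine$flow_l_day,
    urine_conc_mM = sol$urine$conc,
    segmental = segmental,
    segmental_transcellular = seg_trans,
    segmental_paracellular = seg_para,
    segmental_water_l_day = seg_water,
    md_cl_mM = md_cl,
    tna = list(total = unname(tna_total), active = unname(tna_active),
               passive = unname(tna_total - tna_active)),
    glucose = glucose,
    conservation = conservation
  )
  class(rep) <- "kidney_report"
  rep
}

#' @export
print.kidney_report <- function(x, ...) {
  cat("Kidney report:", x$scenario, "\n")
  cat(sprintf("  GFR %.1f L/day, urine %.2f L/day\n", x$gfr_l_day,
              x$urine_l_day))
  df <- data.frame(
    filtered = x$filtered_mmol_day,
    excreted = x$excretion_mmol_day,
    FE = x$fractional_excretion)
  print(round(df, 3))
  cat(sprintf("  Glucose: PCT %.1f%%, S3 %.1f%%, excreted %.1f%% of filtered\n",
              100 * x$glucose$pct_fraction, 100 * x$glucose$s3_fraction,
              100 * x$glucose$fractional_excretion))
  cat(sprintf("  MD [Cl-] superficial %.1f mM; T_Na %.0f (active %.0f) mmol/day\n",
              x$md_cl_mM["superficial"], x$tna$total, x$tna$active))
  invisible(x)
}

#' Macula densa luminal chloride concentration
#'
#' Luminal [Cl-] at the cortical TAL outlet (the model's macula densa
#' locus) for a nephron class.
#'
#' @param sol A `kidney_solution`.
#' @param class_id Nephron class id (default "superficial").
#' @return Concentration in mM.
#' @export
macula_densa_cl <- function(sol, class_id = "superficial") {
  unname(sol$classes[[class_id]]$segments$cTAL$outlet$conc["Cl"])
}

#' Total, active and passive sodium transport
#'
#' Total T_Na is the whole-kidney net transmural Na+ reabsorption; active
#' T_Na is three Na+ per Na/K-ATPase cycle summed over every epithelial
#' cell; passive is the difference (it can be negative in segments with
#' net paracellular secretion).
#'
#' @param sol A `kidney_solution` (or a `kidney_report`).
#' @return List with `total`, `active`, `passive` (mmol/day).
#' @export
tna_split <- function(sol) {
  if (inherits(sol, "kidney_solution")) sol <- kidney_report(sol)
  sol$tna
}

#' Normalize a report by a reference report
#'
#' Element-wise ratios of filtered loads, excretions, urine volume and
#' segmental transport. A zero reference is flagged as `NA` (undefined)
#' rather than evaluated.
#'
#' @param rep,ref `kidney_report` objects with matching structure.
#' @return A list of ratio tables.
#' @export
normalize_report <- function(rep, ref) {
  rt <- function(a, b) {
    out <- a / b
    out[b == 0] <- NA_real_
    out
  }
  list(
    filtered = rt(rep$filtered_mmol_day, ref$filtered_mmol_day),
    excretion = rt(rep$excretion_mmol_day, ref$excretion_mmol_day),
    urine_volume = rt(rep$urine_l_day, ref$urine_l_day),
    segmental = rt(rep$segmental, ref$segmental),
    gfr = rt(rep$gfr_l_day, ref$gfr_l_day),
    tna_total = rt(rep$tna$total, ref$tna$total),
    tna_active = rt(rep$tna$active, ref$tna$active)
  )
}

#' Write figure-style CSV tables for a set of reports
#'
#' Writes the glucose-handling table (filtered, excretion, proximal
#' fractions), the solute/water transport table and, when a reference
#' report is among the inputs, normalized versions (glucose excretion is
#' normalized by the untreated-diabetic value, other quantities by the
#' reference).
#'
#' @param reports Named list of `kidney_report` objects.
#' @param dir Output directory (created if needed).
#' @param ref Name of the reference (non-diabetic) report in `reports`,
#'   or `NULL` to skip normalized tables.
#' @return Invisibly, the paths written.
#' @export
figure_tables <- function(reports, dir, ref = NULL) {
  if (length(reports) == 0) stop("no reports supplied", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()

  glu <- do.call(rbind, lapply(names(reports), function(nm) {
    g <- reports[[nm]]$glucose
    data.frame(scenario = nm,
               filtered_mol_day = g$filtered_mol_day,
               excretion_mol_day = g$excretion_mol_day,
               fe_pct = 100 * g$fractional_excretion,
               pct_reab_pct = 100 * g$pct_fraction,
               s3_reab_pct = 100 * g$s3_fraction)
  }))
  p <- file.path(dir, "glucose_handling.csv")
  utils::write.csv(glu, p, row.names = FALSE)
  paths <- c(paths, p)

  tr <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(scenario = nm, solute = .ns_solutes,
               filtered_mmol_day = as.numeric(r$filtered_mmol_day[.ns_solutes]),
               excretion_mmol_day = as.numeric(r$excretion_mmol_day[.ns_solutes]),
               fe = as.numeric(r$fractional_excretion[.ns_solutes]))
  }))
  p <- file.path(dir, "transport.csv")
  utils::write.csv(tr, p, row.names = FALSE)
  paths <- c(paths, p)

  seg <- do.call(rbind, lapply(names(reports), function(nm) {
    m <- reports[[nm]]$segmental
    data.frame(scenario = nm,
               segment = rep(rownames(m), ncol(m)),
               solute = rep(colnames(m), each = nrow(m)),
               reab_mmol_day = as.numeric(m))
  }))
  p <- file.path(dir, "segmental.csv")
  utils::write.csv(seg, p, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(ref) && ref %in% names(reports)) {
    nrm <- do.call(rbind, lapply(names(reports), function(nm) {
      n <- normalize_report(reports[[nm]], reports[[ref]])
      data.frame(scenario = nm, quantity = c(
        paste0("filtered_", .ns_solutes), paste0("excretion_", .ns_solutes),
        "urine_volume", "gfr", "tna_total", "tna_active"),
        ratio = c(as.numeric(n$filtered[.ns_solutes]),
                  as.numeric(n$excretion[.ns_solutes]),
                  n$urine_volume, n$gfr, n$tna_total, n$tna_active))
    }))
    p <- file.path(dir, "normalized.csv")
    utils::write.csv(nrm, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Tidy axial profiles from a kidney solution
#'
#' @param sol A `kidney_solution`.
#' @return A data.frame with columns scenario, class, segment, x_cm,
#'   Fv_nl_min (per tubule), P_mmHg, V_te_mV, and one `c_<solute>_mM`
#'   column per solute.
#' @export
profiles_df <- function(sol) {
  rows <- list()
  grab <- function(class_id, seg, per_duct = 1) {
    df <- data.frame(scenario = sol$ctx$scenario$name, class = class_id,
                     segment = seg$name, x_cm = seg$x,
                     Fv_nl_min = seg$Fv / per_duct / .ns_const$NL_MIN_TO_ML_S,
                     P_mmHg = seg$P, V_te_mV = seg$v_te)
    cm <- as.data.frame(seg$conc)
    names(cm) <- paste0("c_", .ns_lum, "_mM")
    cbind(df, cm)
  }
  for (nm in names(sol$classes))
    for (sg in sol$classes[[nm]]$segments)
      rows[[length(rows) + 1]] <- grab(nm, sg)
  for (sg in sol$cd)
    rows[[length(rows) + 1]] <- grab("collecting_duct", sg, sg$n_ducts)
  do.call(rbind, rows)
}
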