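# Nephron chaining and whole-kidney assembly.

segment_depth_range <- function(seg_id, turn_cm, om, im) {
  switch(seg_id,
    SDL = c(0, om),
    LDL = c(om, om + turn_cm),
    LAL = c(om + turn_cm, om),
    mTAL = c(om, 0),
    OMCD = c(0, om),
    IMCD = c(om, om + im),
    c(0, 0))
}

# Reference proximal flow profiles for the flow(torque) effect: the
# non-diabetic baseline solved with the torque sensitivity off. Stored in
# the parameter file; computed lazily (and memoized) when absent.
get_torque_reference <- function(params, arch) {
  ref <- params$torque$reference
  if (!is.null(ref)) {
    return(lapply(ref, function(cl) lapply(cl, function(sg)
      list(frac = as.numeric(sg$frac), q = as.numeric(sg$q),
           r_ref = as.numeric(sg$r_ref)))))
  }
  nums <- suppressWarnings(as.numeric(unlist(params, use.names = FALSE)))
  nums <- nums[is.finite(nums)]
  key <- paste(signif(nums, 8), collapse = ",")
  key <- paste0(nchar(key), "|", sum(nums %% 997), "|", substr(key, 1, 200))
  hit <- .ns_cache$torque_ref[[key]]
  if (!is.null(hit)) return(hit)
  p0 <- params
  p0$torque$c_t <- 0
  ctx0 <- apply_scenario(p0, arch, nondiabetic())
  out <- list()
  for (i in seq_len(nrow(arch$nephron_classes))) {
    cl_id <- arch$nephron_classes$id[i]
    sols <- solve_nephron(cl_id, ctx0, torque_ref = NULL,
                          stop_after = "S3")
    out[[cl_id]] <- lapply(sols$segments, function(s) {
      list(frac = s$x / max(s$x), q = s$Fv,
           r_ref = attr(s, "radius"))
    })
  }
  if (is.null(.ns_cache$torque_ref)) .ns_cache$torque_ref <- list()
  .ns_cache$torque_ref[[key]] <- out
  out
}

#' Compute and embed the torque reference profiles in a parameter list
#'
#' Solves the proximal segments of every nephron class under the
#' non-diabetic baseline with the flow(torque) sensitivity switched off,
#' and stores the resulting flow profiles as the reference operating point
#' for torque-dependent transporter scaling.
#'
#' @param params A `nephro_params` list.
#' @param arch A `kidney_architecture`.
#' @return The parameter list with `torque$reference` filled in.
#' @export
embed_torque_reference <- function(params, arch = build_default_architecture()) {
  p0 <- params
  p0$torque$reference <- NULL
  ref <- get_torque_reference(p0, arch)
  params$torque$reference <- lapply(ref, function(cl)
    lapply(cl, function(sg)
      list(frac = as.numeric(sg$frac), q = as.numeric(sg$q),
           r_ref = as.numeric(sg$r_ref))))
  params
}

#' Solve one nephron class from the glomerulus to the connecting tubule
#'
#' Chains the class's segments: the first segment's inlet carries the
#' (scenario-adjusted) SNGFR with protein-free-plasma composition;
#' descending and thin limbs use the no-cell transmural formulation.
#'
#' @param class_id Nephron class id ("superficial", "jm1".."jm5").
#' @param ctx A `solve_context` from [apply_scenario()].
#' @param torque_ref Reference flow profiles (from the context's baseline);
#'   `NULL` disables the torque effect.
#' @param stop_after Optional segment id after which to stop (used for the
#'   reference solve and for proximal-only studies).
#' @return List with `class_id`, `segments` (named list of
#'   `segment_solution`s in order) and the inlet description.
#' @export
solve_nephron <- function(class_id, ctx, torque_ref = NULL,
                          stop_after = NULL) {
  arch <- ctx$arch
  params <- ctx$params
  i <- match(class_id, arch$nephron_classes$id)
  if (is.na(i)) stop("unknown nephron class: ", class_id, call. = FALSE)
  turn <- arch$nephron_classes$loop_turn_depth_mm[i] / 10
  segs <- arch$segments[[class_id]]
  # per-class capacity overrides (juxtamedullary TAL scaling)
  if (grepl("^jm", class_id) && !is.null(params$jm_scaling)) {
    for (r in params$jm_scaling)
      params <- set_param(params, r$path,
                          get_param(params, r$path) * r$factor)
  }
  inlet <- list(flow = arch$nephron_classes$sngfr_nl_min[i] *
                  .ns_const$NL_MIN_TO_ML_S,
                conc = params$plasma,
                pressure = params$inlet_pressure_mmHg %||% 13)
  sols <- list()
  guess <- NULL
  prev_name <- ""
  for (k in seq_len(nrow(segs))) {
    row <- segs[k, ]
    sid <- row$segment_id
    if (sid %in% c("LDL", "LAL") && turn <= 0) next
    tr <- if (!is.null(torque_ref)) torque_ref[[class_id]][[sid]] else NULL
    sp <- compile_segment(
      sid, params,
      length_cm = if (sid %in% c("LDL", "LAL")) turn else row$length_cm,
      diameter_cm = row$inner_diameter_cm,
      grid_points = row$grid_points,
      depth_range = segment_depth_range(sid, turn, arch$om_depth_cm,
                                        arch$im_depth_cm),
      sglt2_inhibition = ctx$sglt2_inhibition,
      pump_axial = ctx$pump_axial[[sid]],
      torque_ref = tr,
      om_depth_cm = arch$om_depth_cm, im_depth_cm = arch$im_depth_cm)
    same_family <- (prev_name %in% c("PCT", "S3") && sid %in% c("PCT", "S3")) ||
      (prev_name %in% c("mTAL", "cTAL") && sid %in% c("mTAL", "cTAL"))
    sol <- solve_segment(inlet, sp,
                         cell_guess = if (same_family) guess else NULL)
    attr(sol, "radius") <- sp$r
    sols[[sid]] <- sol
    inlet <- sol$outlet
    guess <- sol$cell_exit
    prev_name <- sid
    if (!is.null(stop_after) && sid == stop_after) break
  }
  list(class_id = class_id, segments = sols,
       sngfr_ml_s = arch$nephron_classes$sngfr_nl_min[i] *
         .ns_const$NL_MIN_TO_ML_S)
}

#' Solve the whole model kidney for a scenario
#'
#' Solves all six nephron classes, merges the connecting-tubule outflows
#' (population-weighted, 10:1 loop-to-CCD coalescence) into the cortical
#' collecting duct, and carries the shared collecting duct through the
#' outer and inner medulla with successive duct merges. The collecting
#' duct is solved in kidney-total flow units, so merge nodes conserve
#' water and solute flows identically.
#'
#' @param scenario A `scenario` object.
#' @param params Baseline parameters (default: packaged file).
#' @param arch Baseline architecture (default: [build_default_architecture()]).
#' @param grid_mult Grid-refinement multiplier.
#' @return A `kidney_solution`: per-class nephron solutions (`classes`),
#'   collecting-duct solutions (`cd`), urine flow and composition
#'   (`urine`), the solve context, and nephron counts per class.
#' @export
#' @examples
#' \donttest{
#' sol <- solve_kidney(nondiabetic())
#' sol$urine$flow_l_day
#' }
solve_kidney <- function(scenario, params = default_params(),
                         arch = build_default_architecture(),
                         grid_mult = 1) {
  ctx <- apply_scenario(params, arch, scenario, grid_mult)
  tref <- get_torque_reference(params, arch)
  cls <- ctx$arch$nephron_classes
  counts <- cls$population_fraction * ctx$arch$total_nephrons

  classes <- list()
  for (i in seq_len(nrow(cls))) {
    classes[[cls$id[i]]] <- solve_nephron(cls$id[i], ctx, torque_ref = tref)
  }

  # merge CNT outflows into the shared collecting duct (kidney-scale)
  flows <- vapply(classes, function(s) s$segments$CNT$outlet$flow, 0)
  concs <- t(vapply(classes,
                    function(s) as.numeric(s$segments$CNT$outlet$conc),
                    numeric(6)))
  merged <- merge_streams(flows, concs, weights = counts)
  n_ccd <- ctx$arch$total_nephrons / ctx$arch$topology$cnt_merge_ratio

  cd_tab <- ctx$arch$segments$collecting_duct
  sched <- ctx$arch$topology$imcd_merge_schedule
  inlet <- list(flow = merged$flow,
                conc = stats::setNames(merged$conc, .ns_lum),
                pressure = 10)
  cd <- list()
  guess <- NULL
  for (k in seq_len(nrow(cd_tab))) {
    row <- cd_tab[k, ]
    sid <- row$segment_id
    np <- row$grid_points + 1
    if (sid == "IMCD") {
      frac <- seq(0, 1, length.out = np)
      divisor <- vapply(frac, function(f)
        prod(sched$merge_factor[sched$depth_fraction <= f + 1e-12]), 0)
      nd <- n_ccd / divisor
    } else {
      nd <- rep(n_ccd, np)
    }
    sp <- compile_segment(
      sid, ctx$params,
      length_cm = row$length_cm, diameter_cm = row$inner_diameter_cm,
      grid_points = row$grid_points,
      depth_range = segment_depth_range(sid, 0, ctx$arch$om_depth_cm,
                                        ctx$arch$im_depth_cm),
      n_ducts = nd,
      sglt2_inhibition = ctx$sglt2_inhibition,
      pump_axial = ctx$pump_axial[[sid]],
      om_depth_cm = ctx$arch$om_depth_cm, im_depth_cm = ctx$arch$im_depth_cm)
    sol <- solve_segment(inlet, sp, cell_guess = guess)
    attr(sol, "radius") <- sp$r
    cd[[sid]] <- sol
    inlet <- sol$outlet
    guess <- sol$cell_exit
  }

  urine_flow <- inlet$flow   # kidney-total cm^3/s
  out <- list(
    classes = classes, cd = cd,
    counts = stats::setNames(counts, cls$id),
    ctx = ctx,
    cd_inlet = merged,
    urine = list(flow_ml_s = urine_flow,
                 flow_l_day = urine_flow * .ns_const$ML_S_TO_L_DAY,
                 conc = inlet$conc,
                 excretion_mmol_day = stats::setNames(
                   urine_flow * as.numeric(inlet$conc) *
                     .ns_const$UMOL_S_TO_MMOL_DAY, .ns_lum))
  )
  class(out) <- "kidney_solution"
  out
}
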