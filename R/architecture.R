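# Nephron population, segment chain, geometry and coalescence topology.

.ns_segment_ids <- c("PCT", "S3", "SDL", "LDL", "LAL", "mTAL", "cTAL",
                     "DCT", "CNT", "CCD", "OMCD", "IMCD")

#' Build the default six-class kidney architecture
#'
#' Constructs the model kidney: one superficial nephron class (85% of the
#' population, loop turning at the outer-inner medullary boundary) and five
#' juxtamedullary classes (15% combined) whose loops of Henle reach to
#' staggered depths of the inner medulla, with most long loops turning in
#' the upper inner medulla. Connecting tubules coalesce 10:1 into cortical
#' collecting ducts; the inner-medullary collecting duct merges pairwise at
#' evenly spaced depths.
#'
#' @param total_nephrons Total nephron count per kidney (default 1e6).
#' @param sngfr_superficial,sngfr_juxtamedullary Single-nephron GFR in
#'   nL/min for the superficial and juxtamedullary classes (defaults 100
#'   and 133).
#' @param grid_points Number of axial grid intervals per segment
#'   (must be >= 20; default 40).
#' @return An object of class `kidney_architecture`: a list with elements
#'   `nephron_classes` (data.frame: id, population_fraction, sngfr_nl_min,
#'   loop_turn_depth_mm), `segments` (named list of per-class data.frames
#'   with columns segment_id, length_cm, inner_diameter_cm, grid_points),
#'   `topology` (cnt_merge_ratio, imcd_merge_schedule), `total_nephrons`,
#'   and medullary depths `om_depth_cm`, `im_depth_cm`.
#' @export
#' @examples
#' arch <- build_default_architecture()
#' nrow(arch$nephron_classes)   # 6
#' single_kidney_gfr(arch)$ml_min
build_default_architecture <- function(total_nephrons = 1e6,
                                       sngfr_superficial = 100,
                                       sngfr_juxtamedullary = 133,
                                       grid_points = 40) {
  if (grid_points < 20) stop("grid_points must be >= 20", call. = FALSE)
  om <- 0.7   # outer medullary depth, cm
  im <- 2.0   # inner medullary depth, cm

  jm_frac <- c(0.06, 0.04, 0.025, 0.02, 0.005)
  jm_turn <- c(0.2, 0.4, 0.6, 0.8, 1.0) * im      # cm below OM-IM boundary
  cls <- data.frame(
    id = c("superficial", paste0("jm", 1:5)),
    population_fraction = c(0.85, jm_frac),
    sngfr_nl_min = c(sngfr_superficial, rep(sngfr_juxtamedullary, 5)),
    loop_turn_depth_mm = c(0, jm_turn * 10),
    stringsAsFactors = FALSE
  )

  base_geom <- function(seg, len, diam_um, grid_mult_seg = 1) {
    data.frame(segment_id = seg, length_cm = len,
               inner_diameter_cm = diam_um * 1e-4,
               grid_points = as.integer(round(grid_points * grid_mult_seg)),
               stringsAsFactors = FALSE)
  }

  seg_list <- list()
  for (i in seq_len(nrow(cls))) {
    id <- cls$id[i]
    turn <- cls$loop_turn_depth_mm[i] / 10
    if (id == "superficial") {
      segs <- rbind(
        base_geom("PCT", 1.0, 25),
        base_geom("S3", 0.5, 22),
        base_geom("SDL", om, 15),
        base_geom("mTAL", om, 20),
        base_geom("cTAL", 0.5, 20),
        base_geom("DCT", 0.5, 17),
        base_geom("CNT", 0.5, 20, 1.6)
      )
    } else {
      segs <- rbind(
        base_geom("PCT", 1.0, 25),
        base_geom("S3", 0.5, 22),
        base_geom("SDL", om, 15),
        base_geom("LDL", turn, 15),
        base_geom("LAL", turn, 15),
        base_geom("mTAL", om, 20),
        base_geom("cTAL", 0.5, 20),
        base_geom("DCT", 0.5, 17),
        base_geom("CNT", 0.5, 20, 1.6)
      )
    }
    seg_list[[id]] <- segs
  }
  # Shared collecting duct (solved once, kidney-scaled)
  # water-equilibrating distal segments carry steeper osmotic boundary
  # layers and get proportionally finer default grids
  seg_list[["collecting_duct"]] <- rbind(
    base_geom("CCD", 0.5, 22, 1.6),
    base_geom("OMCD", om, 22, 2.0),
    base_geom("IMCD", im, 28, 3.2)
  )

  arch <- list(
    nephron_classes = cls,
    segments = seg_list,
    topology = list(
      cnt_merge_ratio = 10,
      # (fraction of IMCD length, merge factor)
      imcd_merge_schedule = data.frame(depth_fraction = c(0.2, 0.4, 0.6, 0.8),
                                       merge_factor = c(2, 2, 2, 2))
    ),
    total_nephrons = total_nephrons,
    om_depth_cm = om,
    im_depth_cm = im
  )
  class(arch) <- "kidney_architecture"
  validate_architecture(arch)
  arch
}

#' Validate a kidney architecture
#'
#' Checks the structural invariants: population fractions sum to one,
#' positive SNGFRs and geometry, and the segment chain ordering.
#'
#' @param arch A `kidney_architecture`.
#' @return `arch`, invisibly; errors if an invariant is violated.
#' @export
validate_architecture <- function(arch) {
  cls <- arch$nephron_classes
  if (abs(sum(cls$population_fraction) - 1) > 1e-12)
    stop("population fractions must sum to 1", call. = FALSE)
  if (any(cls$sngfr_nl_min <= 0)) stop("sngfr must be positive", call. = FALSE)
  for (nm in names(arch$segments)) {
    g <- arch$segments[[nm]]
    if (any(g$length_cm <= 0) || any(g$inner_diameter_cm <= 0))
      stop("segment geometry must be strictly positive", call. = FALSE)
    if (any(!g$segment_id %in% .ns_segment_ids))
      stop("unknown segment id in class ", nm, call. = FALSE)
    if (any(g$grid_points < 20))
      stop("grid_points must be >= 20", call. = FALSE)
  }
  invisible(arch)
}

#' Single-kidney glomerular filtration rate
#'
#' Population-weighted sum of single-nephron GFRs over all nephron classes,
#' scaled by the total nephron count.
#'
#' @param arch A `kidney_architecture`.
#' @return A list with `ml_min` (mL/min) and `l_day` (L/day).
#' @export
#' @examples
#' single_kidney_gfr(build_default_architecture())
single_kidney_gfr <- function(arch) {
  cls <- arch$nephron_classes
  nl_min <- arch$total_nephrons * sum(cls$population_fraction * cls$sngfr_nl_min)
  ml_min <- nl_min * 1e-6
  list(ml_min = ml_min, l_day = ml_min * 1440 / 1000)
}

#' Scale segment geometry
#'
#' Returns a new architecture with the selected segments' diameters and/or
#' lengths multiplied; the input is unchanged. Used by the diabetes
#' scenarios to represent tubular hypertrophy.
#'
#' @param arch A `kidney_architecture`.
#' @param segment_selector Character vector of segment ids, or one of the
#'   keywords `"proximal"` (PCT, S3) or `"distal"` (DCT through IMCD).
#' @param diameter_multiplier,length_multiplier Positive scale factors.
#' @return A new `kidney_architecture`.
#' @export
#' @examples
#' a <- scale_geometry(build_default_architecture(), "proximal", 1.1, 1.1)
scale_geometry <- function(arch, segment_selector,
                           diameter_multiplier = 1, length_multiplier = 1) {
  if (diameter_multiplier <= 0 || length_multiplier <= 0)
    stop("geometry multipliers must be positive", call. = FALSE)
  segs <- resolve_segment_selector(segment_selector)
  out <- arch
  for (nm in names(out$segments)) {
    g <- out$segments[[nm]]
    hit <- g$segment_id %in% segs
    g$inner_diameter_cm[hit] <- g$inner_diameter_cm[hit] * diameter_multiplier
    g$length_cm[hit] <- g$length_cm[hit] * length_multiplier
    out$segments[[nm]] <- g
  }
  out
}

resolve_segment_selector <- function(sel) {
  if (length(sel) == 1 && sel == "proximal") return(c("PCT", "S3"))
  if (length(sel) == 1 && sel == "distal")
    return(c("DCT", "CNT", "CCD", "OMCD", "IMCD"))
  bad <- setdiff(sel, .ns_segment_ids)
  if (length(bad)) stop("unknown segment id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sel
}

#' Merge tubular streams at a coalescence node
#'
#' Population-weighted merge of water and solute flows from several
#' upstream streams into one downstream stream. Total flow of water and of
#' every solute is conserved exactly; the merged concentration is the
#' flow-weighted mean.
#'
#' @param flows Numeric vector of upstream water flows (one per stream).
#' @param concs Matrix of upstream concentrations, streams in rows,
#'   solutes in columns.
#' @param weights Numeric vector of stream multiplicities (e.g. nephron
#'   counts feeding the node).
#' @return List with `flow` (total water flow) and `conc` (merged
#'   concentration vector).
#' @export
merge_streams <- function(flows, concs, weights = rep(1, length(flows))) {
  concs <- rbind(concs)
  total <- sum(weights * flows)
  if (total <= 0) stop("merged flow must be positive", call. = FALSE)
  solute_flows <- colSums(concs * (weights * flows))
  list(flow = total, conc = solute_flows / total)
}

#' @export
print.kidney_architecture <- function(x, ...) {
  g <- single_kidney_gfr(x)
  cat("Kidney architecture:", nrow(x$nephron_classes), "nephron classes,",
      format(x$total_nephrons, big.mark = ","), "nephrons\n")
  cat(sprintf("Single-kidney GFR: %.2f mL/min (%.1f L/day)\n",
              g$ml_min, g$l_day))
  print(x$nephron_classes, row.names = FALSE)
  cat("\nCNT merge ratio", x$topology$cnt_merge_ratio, ": 1 into CCD;",
      nrow(x$topology$imcd_merge_schedule), "IMCD merge nodes\n")
  invisible(x)
}

#' Serialize / deserialize an architecture
#'
#' @param arch A `kidney_architecture`.
#' @param path File path for the YAML representation.
#' @return `read_architecture` returns a `kidney_architecture`.
#' @export
write_architecture <- function(arch, path) {
  obj <- unclass(arch)
  obj$segments <- lapply(obj$segments, function(g) as.list(g))
  obj$nephron_classes <- as.list(obj$nephron_classes)
  obj$topology$imcd_merge_schedule <- as.list(obj$topology$imcd_merge_schedule)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$nephron_classes <- as.data.frame(obj$nephron_classes,
                                       stringsAsFactors = FALSE)
  obj$segments <- lapply(obj$segments, function(g)
    as.data.frame(g, stringsAsFactors = FALSE))
  obj$topology$imcd_merge_schedule <-
    as.data.frame(obj$topology$imcd_merge_schedule)
  class(obj) <- "kidney_architecture"
  validate_architecture(obj)
  obj
}
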