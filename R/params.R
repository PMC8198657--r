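# Baseline parameter file handling.
#
# All transport parameters (transporter capacities, affinities, channel and
# paracellular permeabilities, water permeabilities, interstitial gradient,
# torque sensitivity) live in one versioned YAML config shipped with the
# package. Every value is addressable by a dot-separated path for overrides
# and calibration.

#' Load the baseline model parameters
#'
#' Reads the packaged (or a user-supplied) YAML parameter file. The file
#' holds plasma composition, the interstitial osmotic gradient, torque
#' sensitivity and per-segment transporter/permeability parameters.
#'
#' @param path Path to a YAML parameter file; defaults to the packaged
#'   baseline file.
#' @return A nested list of class `nephro_params`.
#' @export
#' @examples
#' p <- default_params()
#' p$plasma$glucose   # 5 mM non-diabetic
default_params <- function(path = system.file("extdata",
                                              "default_params.yaml",
                                              package = "nephrosim")) {
  if (!nzchar(path) || !file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  p <- yaml::read_yaml(path)
  pl <- unlist(p$plasma)[.ns_solutes]
  # background anion closes plasma (and filtrate) electroneutrality
  p$plasma <- c(pl, anion = unname(pl["Na"] + pl["K"] - pl["Cl"]))
  class(p) <- "nephro_params"
  p
}

#' Get or set a parameter by path
#'
#' @param params A `nephro_params` list.
#' @param path Dot-separated path, e.g. `"segments.PCT.apical.sglt.vmax"`.
#' @param value Replacement value (for `set_param`).
#' @return `get_param` returns the value; `set_param` returns the modified
#'   parameter list (the input is unchanged).
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- params
  for (k in keys) {
    if (is.null(out[[k]])) stop("unknown parameter path: ", path, call. = FALSE)
    out <- out[[k]]
  }
  out
}

#' @rdname get_param
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[keys]] <- value
  params
}

#' Write a parameter list back to YAML
#'
#' @param params A `nephro_params` list.
#' @param path Output file path.
#' @export
write_params <- function(params, path) {
  p <- unclass(params)
  p$plasma <- as.list(p$plasma)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' Interstitial concentration profile
#'
#' The model interstitium (boundary condition for basolateral and
#' paracellular fluxes): cortical composition equals plasma; osmolality
#' rises piecewise-linearly from its cortical value at the corticomedullary
#' boundary to `om_boundary_osm` at the outer-inner medullary boundary
#' (NaCl-driven) and on to `tip_osm` at the papillary tip (half NaCl, half
#' urea). Interstitial K and glucose are held at plasma values.
#'
#' @param depth_cm Depth below the corticomedullary boundary (cm);
#'   0 or negative = cortex.
#' @param params A `nephro_params` list.
#' @param om_depth_cm Outer medullary depth (cm).
#' @param im_depth_cm Inner medullary depth (cm).
#' @return Named concentration vector (mM) over the model solutes plus
#'   the background anion.
#' @export
interstitial_conc <- function(depth_cm, params, om_depth_cm = 0.7,
                              im_depth_cm = 2.0) {
  pl <- params$plasma
  it <- params$interstitium
  cortex_osm <- sum(pl) + params$background_osmoles
  c_int <- pl
  if (depth_cm <= 0) return(c_int)
  if (depth_cm <= om_depth_cm) {
    dosm <- (it$om_boundary_osm - cortex_osm) * depth_cm / om_depth_cm
    c_int["Na"] <- c_int["Na"] + dosm / 2
    c_int["Cl"] <- c_int["Cl"] + dosm / 2
  } else {
    dosm_om <- it$om_boundary_osm - cortex_osm
    frac <- min((depth_cm - om_depth_cm) / im_depth_cm, 1)
    dosm_im <- (it$tip_osm - it$om_boundary_osm) * frac
    uf <- it$im_urea_fraction
    c_int["Na"] <- c_int["Na"] + dosm_om / 2 + (1 - uf) * dosm_im / 2
    c_int["Cl"] <- c_int["Cl"] + dosm_om / 2 + (1 - uf) * dosm_im / 2
    c_int["urea"] <- c_int["urea"] + uf * dosm_im
  }
  c_int
}
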