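# Shared lazily-computed solutions: the two-stage calibration and the
# scenario solves are expensive, so tests share one cached copy.

.tcache <- new.env(parent = emptyenv())

calibrated_params <- function() {
  if (is.null(.tcache$params)) {
    cal <- calibrate(rounds = 2, report = FALSE)
    .tcache$params <- cal$params
  }
  .tcache$params
}

scenario_solution <- function(key, grid_mult = 1) {
  id <- paste0(key, "_sol_g", grid_mult)
  if (is.null(.tcache[[id]])) {
    sc <- switch(key,
                 nd = nondiabetic(),
                 ndi = with_sglt2i(nondiabetic()),
                 mod = moderate_diabetes(),
                 sev = severe_diabetes(),
                 modi = with_sglt2i(moderate_diabetes()),
                 sevi = with_sglt2i(severe_diabetes()))
    .tcache[[id]] <- solve_kidney(sc, calibrated_params(),
                                  grid_mult = grid_mult)
  }
  .tcache[[id]]
}

scenario_report <- function(key, grid_mult = 1) {
  id <- paste0(key, "_rep_g", grid_mult)
  if (is.null(.tcache[[id]]))
    .tcache[[id]] <- kidney_report(scenario_solution(key, grid_mult))
  .tcache[[id]]
}

baseline_pct_spec <- function(params = default_params()) {
  compile_segment("PCT", params)
}

# parameters with every transport pathway silenced for a given segment
silence_segment <- function(params, seg) {
  s <- params$segments[[seg]]
  zero_all <- function(x) {
    for (nm in names(x)) {
      if (is.list(x[[nm]])) {
        if (!is.null(x[[nm]]$vmax)) x[[nm]]$vmax <- 0
        else x[[nm]] <- lapply(x[[nm]], function(v)
          if (is.numeric(v)) 0 * v else v)
      } else if (is.numeric(x[[nm]]) && !grepl("km|beta", nm)) {
        x[[nm]] <- 0
      }
    }
    x
  }
  if (!is.null(s$apical)) s$apical <- zero_all(s$apical)
  if (!is.null(s$basolateral)) s$basolateral <- zero_all(s$basolateral)
  s$paracellular$p <- lapply(s$paracellular$p, function(v) 0)
  s$paracellular$pf <- 0
  s$pf_trans <- 0
  s$background_p <- 0
  params$segments[[seg]] <- s
  params
}
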