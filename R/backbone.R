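#' Load a backbone biophysics configuration
#'
#' The backbone configuration defines the passive properties and the
#' voltage-gated channel complement of the dendritic shaft, soma and axon
#' as a generic Hodgkin-Huxley schema: each mechanism has a reversal
#' potential, per-region densities (mS/cm^2) with an optional linear
#' path-distance gradient, and one or two gates with Boltzmann steady
#' states and constant or bell-shaped time constants. The shipped default
#' (\code{backbone_synthetic.json}) is a synthetic profile calibrated once
#' to produce a propagating, distance-attenuating backpropagating action
#' potential on the synthetic CA1 morphology; a second profile slot can
#' hold a full reproduction parameter set.
#'
#' On load the L-type rule is recorded: the density of the L-type-like
#' calcium mechanism in the first \code{proximal_um} micrometres of the
#' apical shaft is forced equal to its distal density when densities are
#' instantiated per compartment (see \code{\link{build_cell}}).
#'
#' @param path path to a JSON configuration; default is the shipped
#'   synthetic profile.
#' @return a list of class \code{BackboneConfig}.
#' @export
load_backbone_config <- function(path = system.file("extdata",
                                                    "backbone_synthetic.json",
                                                    package = "spinescale")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  validate_backbone(cfg)
  class(cfg) <- "BackboneConfig"
  cfg
}

validate_backbone <- function(cfg) {
  stopifnot(is.list(cfg$passive), is.list(cfg$mechanisms))
  for (m in cfg$mechanisms) {
    stopifnot(!is.null(m$name), !is.null(m$erev_mV),
              all(unlist(m$density_mS_cm2) >= 0))
    for (g in m$gates) {
      stopifnot(g$tau_type %in% c("const", "bell"), all(g$tau[1] > 0))
    }
  }
  invisible(TRUE)
}

region_value <- function(tab, region) {
  if (!is.list(tab) && length(tab) == 1L && is.null(names(tab))) return(tab)
  tab <- unlist(tab)
  if (region %in% names(tab)) unname(tab[[region]])
  else if ("default" %in% names(tab)) unname(tab[["default"]])
  else 0
}

# per-compartment density (mS/cm^2) for one mechanism, applying the
# region table, the optional distance gradient, and the proximal L-type rule
mech_density <- function(mech, comp, ltype_rule = NULL) {
  base <- vapply(comp$region, function(r) region_value(mech$density_mS_cm2, r),
                 numeric(1), USE.NAMES = FALSE)
  dens <- base
  gr <- mech$gradient
  apply_gradient <- function(dist) {
    f <- 1 + gr$per_100um * dist / 100
    pmin(pmax(f, gr$min_factor %||% 0), gr$max_factor %||% Inf)
  }
  if (!is.null(gr)) {
    sel <- comp$region %in% unlist(gr$regions)
    dens[sel] <- base[sel] * apply_gradient(comp$path_dist[sel])
  }
  if (!is.null(ltype_rule) && identical(mech$name, ltype_rule$mechanism)) {
    prox <- comp$region == "apical_trunk" & comp$path_dist < ltype_rule$proximal_um
    if (any(prox)) {
      # density the mechanism has just beyond the proximal border
      ref_base <- region_value(mech$density_mS_cm2, "apical_trunk")
      ref <- if (!is.null(gr) && "apical_trunk" %in% unlist(gr$regions))
        ref_base * apply_gradient(ltype_rule$proximal_um) else ref_base
      dens[prox] <- ref
    }
  }
  dens
}

`%||%` <- function(a, b) if (is.null(a)) b else a
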