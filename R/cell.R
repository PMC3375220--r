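#' Assemble a simulatable cell from morphology, backbone and spines
#'
#' Discretizes the morphology, instantiates the backbone channel densities
#' per compartment (including the proximal L-type equalization rule), and
#' attaches each spine as two extra passive compartments (neck and head;
#' Rm = 10 kOhm cm^2, Ra = 50 Ohm cm) carrying AMPA, NMDA and R-type
#' mechanisms on the head. The initial state is rest: V at the configured
#' resting potential, spine calcium at its resting concentration.
#'
#' @param morph a \code{Morphology}.
#' @param backbone a \code{BackboneConfig} (see
#'   \code{\link{load_backbone_config}}).
#' @param spines data.frame from \code{\link{place_spines}} (may have zero
#'   rows for a plain cable model).
#' @param g_ampa_pS per-spine AMPA peak conductance, pS (recycled).
#' @param nmda an \code{NMDAParams}.
#' @param ampa an \code{AMPAParams} (supplies kinetics and calcium split;
#'   the conductance comes from \code{g_ampa_pS}).
#' @param rtype an \code{RTypeParams}.
#' @param geom a \code{SpineGeometry}.
#' @param caspine a \code{CalciumParams} for the spine head.
#' @param max_seg_len spatial discretization limit, um.
#' @return an object of class \code{Cell}: the immutable model description
#'   passed to the integrator, plus a \code{spine} table with attachment
#'   metadata (path distance, region, head compartment).
#' @export
build_cell <- function(morph, backbone = load_backbone_config(),
                       spines = NULL, g_ampa_pS = 200,
                       nmda = nmda_params(), ampa = ampa_params(),
                       rtype = rtype_params(), geom = spine_geometry(),
                       caspine = calcium_params(), max_seg_len = 10) {
  ra_tab <- unlist(backbone$passive$ra_ohm_cm)
  cg <- discretize(morph, max_seg_len, ra_ohm_cm = as.list(ra_tab))
  comp <- cg$comp
  nd <- nrow(comp)
  area_cm2 <- comp$area_um2 / PHYS$UM2_PER_CM2
  rm_ohm_cm2 <- vapply(comp$region, function(r)
    1e3 * region_value(backbone$passive$rm_kohm_cm2, r), numeric(1))
  cm_nF <- area_cm2 * backbone$passive$cm_uF_cm2 * 1e3
  g_pas_uS <- area_cm2 / rm_ohm_cm2 * 1e6
  e_pas <- rep(backbone$passive$e_pas_mV, nd)
  parent <- cg$parent
  g_ax <- cg$g_axial_uS

  mechs <- lapply(backbone$mechanisms, function(m) {
    dens <- mech_density(m, comp, backbone$ltype_rule)
    gates <- lapply(m$gates, function(g) {
      list(power = g$power, inf_vhalf = g$inf_vhalf, inf_k = g$inf_k,
           tau_type = if (identical(g$tau_type, "bell")) 1L else 0L,
           tau = as.numeric(unlist(g$tau)),
           tau_scale = g$q10_tau_scale %||% 1.0)
    })
    list(name = m$name, erev_mV = m$erev_mV,
         is_calcium = isTRUE(m$is_calcium),
         gbar_uS = dens * area_cm2 * 1e3,   # mS/cm2 * cm2 = mS = 1e3 uS
         gates = gates)
  })

  # ---- spines: two extra compartments each ----
  if (is.null(spines)) spines <- data.frame()
  nsp <- nrow(spines)
  spine_rm <- 1e3 * region_value(backbone$passive$rm_kohm_cm2, "spine")
  spine_ra <- region_value(as.list(ra_tab), "spine")
  neck_area <- pi * geom$neck_diam * geom$neck_len
  head_area <- pi * geom$head_diam * geom$head_len
  r_neck <- spine_ra * (geom$neck_len * 1e-4) /
    (pi * (geom$neck_diam / 2)^2 * 1e-8)         # Ohm
  r_head <- spine_ra * (geom$head_len * 1e-4) /
    (pi * (geom$head_diam / 2)^2 * 1e-8)
  neck_comp <- head_comp <- integer(nsp)
  if (nsp > 0) {
    attach_comp <- locate_compartment(cg, spines$section, spines$arc)
    for (s in seq_len(nsp)) {
      neck_comp[s] <- nd + 2L * s - 1L
      head_comp[s] <- nd + 2L * s
    }
    parent <- c(parent, as.integer(rbind(attach_comp, neck_comp)))
    g_ax <- c(g_ax, as.numeric(rbind(
      rep(1e6 / (r_neck / 2), nsp),              # dendrite centre -> neck
      rep(1e6 / (r_neck / 2 + r_head / 2), nsp)  # neck -> head
    )))
    sp_area_cm2 <- rep(c(neck_area, head_area), nsp) / PHYS$UM2_PER_CM2
    cm_nF <- c(cm_nF, sp_area_cm2 * backbone$passive$cm_uF_cm2 * 1e3)
    g_pas_uS <- c(g_pas_uS, sp_area_cm2 / spine_rm * 1e6)
    e_pas <- c(e_pas, rep(backbone$passive$e_pas_mV, 2L * nsp))
    for (i in seq_along(mechs)) {
      mechs[[i]]$gbar_uS <- c(mechs[[i]]$gbar_uS, rep(0, 2L * nsp))
    }
  }

  shaft_cfg <- backbone$shaft_calcium
  shaft_vol <- c(comp$area_um2 * (shaft_cfg$shell_depth_um %||% 0.1),
                 rep(0, 2L * nsp))
  shaft_vol[comp$region %in% c("axon")] <- 0

  spine_tab <- if (nsp > 0) {
    cbind(spines,
          data.frame(neck_comp = neck_comp, head_comp = head_comp,
                     g_ampa_pS = rep_len(g_ampa_pS, nsp)))
  } else {
    data.frame(spine = integer(), section = integer(), arc = numeric(),
               path_dist = numeric(), region = character(),
               neck_comp = integer(), head_comp = integer(),
               g_ampa_pS = numeric())
  }

  rtg <- list(
    list(power = rtype$m_power, inf_vhalf = rtype$m_vhalf, inf_k = rtype$m_k,
         tau_type = 1L, tau = rtype$m_tau, tau_scale = rtype$tau_scale),
    list(power = rtype$h_power, inf_vhalf = rtype$h_vhalf, inf_k = rtype$h_k,
         tau_type = 1L, tau = rtype$h_tau, tau_scale = rtype$tau_scale))

  cell <- structure(list(
    cg = cg,
    n_comp = nd + 2L * nsp,
    n_dend = nd,
    parent0 = as.integer(ifelse(is.na(parent), -1L, parent - 1L)),
    g_axial_uS = ifelse(is.na(g_ax), 0, g_ax),
    cm_nF = cm_nF, g_pas_uS = g_pas_uS, e_pas_mV = e_pas,
    mechanisms = mechs,
    shaft_ca = list(enabled = isTRUE(shaft_cfg$enabled), vol_um3 = shaft_vol,
                    kappa = shaft_cfg$kappa %||% 20,
                    tau_ms = shaft_cfg$tau_ms %||% 20,
                    ca0_mM = shaft_cfg$ca0_mM %||% 7e-5),
    spine = spine_tab,
    nmda = nmda, ampa = ampa, rtype = rtype, rtype_gates_def = rtg,
    geom = geom, caspine = caspine,
    ca_e_mM = caspine$ca_e_mM,
    temp_K = celsius_to_kelvin(backbone$temperature_c %||% 34),
    v_init_mV = backbone$v_init_mV %||% -65,
    ap_threshold_mV = backbone$ap_threshold_mV %||% 0,
    soma_comp = 1L
  ), class = "Cell")
  equilibrate(cell)
}

#' Per-spine AMPA conductances of a cell
#' @param cell a \code{Cell}.
#' @return numeric vector, pS.
#' @export
spine_conductances <- function(cell) cell$spine$g_ampa_pS

#' Replace the per-spine AMPA conductances of a cell
#' @param cell a \code{Cell}.
#' @param g_pS numeric vector of conductances, pS (length = number of
#'   spines); clipped at zero.
#' @return the modified \code{Cell}.
#' @export
set_spine_conductances <- function(cell, g_pS) {
  stopifnot(length(g_pS) == nrow(cell$spine))
  cell$spine$g_ampa_pS <- pmax(0, g_pS)
  cell
}

#' @export
print.Cell <- function(x, ...) {
  cat("Cell:", x$n_dend, "dendritic compartments,", nrow(x$spine),
      "spines (", x$n_comp, "compartments total )\n")
  invisible(x)
}
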