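#' Spatially discretize a Morphology into electrical compartments
#'
#' Each section is divided into at least \code{ceiling(length / max_seg_len)}
#' compartments. Compartment membrane area uses the lateral surface of the
#' tapered frustum spanned by the compartment; axial resistances use the
#' exact frustum formula \eqn{R = Ra L / (\pi r_1 r_2)}. Coupling
#' conductances connect compartment centres through the two half-resistances.
#' A single-point soma is treated as a sphere represented by an equivalent
#' cylinder (L = diam), which preserves its surface area.
#'
#' @param morph a \code{Morphology}.
#' @param max_seg_len maximum compartment length in um (> 0).
#' @param ra_ohm_cm axial resistivity, Ohm cm; scalar or named per-region.
#' @return an object of class \code{CompartmentGraph}: a list with
#'   \code{comp} (data.frame: section, arc0, arc1, arc_mid, length, diam,
#'   area_um2, path_dist, region), \code{parent} (index of the parent
#'   compartment, NA for the root) and \code{g_axial_uS} (coupling to the
#'   parent, uS).
#' @export
discretize <- function(morph, max_seg_len = 10, ra_ohm_cm = 50) {
  stopifnot(max_seg_len > 0)
  ra_of <- function(region) {
    if (length(ra_ohm_cm) == 1L && is.null(names(ra_ohm_cm))) return(ra_ohm_cm)
    if (region %in% names(ra_ohm_cm)) ra_ohm_cm[[region]] else ra_ohm_cm[["default"]]
  }
  rows <- list(); parent <- integer(0); rhalf0 <- numeric(0); rhalf1 <- numeric(0)
  first_comp <- integer(length(morph$sections))
  last_comp <- integer(length(morph$sections))
  k <- 0L
  for (s in morph$sections) {
    single_point <- nrow(s$points) == 1L
    L <- if (single_point) s$diam[1] else s$length     # point soma -> sphere
    nseg <- max(1L, ceiling(L / max_seg_len))
    bounds <- seq(0, 1, length.out = nseg + 1L)
    r_at <- function(a) {
      if (single_point) return(s$diam[1] / 2)
      approx(s$cum_len, s$diam / 2, xout = a * s$length, rule = 2)$y
    }
    ra <- ra_of(s$region)
    for (j in seq_len(nseg)) {
      a0 <- bounds[j]; a1 <- bounds[j + 1L]
      len <- L / nseg
      r0 <- r_at(a0); r1 <- r_at(a1)
      slant <- sqrt(len^2 + (r1 - r0)^2)
      area <- pi * (r0 + r1) * slant
      # half axial resistances in Ohm (lengths um -> cm: 1e-4)
      rm <- (r0 + r1) / 2
      rh0 <- ra * (len / 2) * 1e-4 / (pi * r0 * rm * 1e-8)
      rh1 <- ra * (len / 2) * 1e-4 / (pi * rm * r1 * 1e-8)
      k <- k + 1L
      rows[[k]] <- data.frame(
        section = s$id, arc0 = a0, arc1 = a1, arc_mid = (a0 + a1) / 2,
        length = len, diam = r0 + r1, area_um2 = area,
        path_dist = s$start_dist + (a0 + a1) / 2 * s$length,
        region = s$region)
      parent[k] <- if (j > 1L) k - 1L else {
        if (is.na(s$parent_section)) NA_integer_ else last_comp[s$parent_section]
      }
      rhalf0[k] <- rh0; rhalf1[k] <- rh1
      if (j == 1L) first_comp[s$id] <- k
    }
    last_comp[s$id] <- k
  }
  comp <- do.call(rbind, rows)
  g_axial <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    p <- parent[i]
    if (is.na(p)) next
    rtot <- rhalf0[i] + rhalf1[p]   # Ohm
    g_axial[i] <- 1e6 / rtot        # uS
  }
  structure(list(comp = comp, parent = parent, g_axial_uS = g_axial,
                 first_comp = first_comp, last_comp = last_comp,
                 morph = morph, max_seg_len = max_seg_len),
            class = "CompartmentGraph")
}

#' Total membrane area of a CompartmentGraph, um^2
#' @param cg a \code{CompartmentGraph}.
#' @return total area in um^2.
#' @export
total_area <- function(cg) sum(cg$comp$area_um2)

#' Find the compartment containing a (section, arc) location
#' @param cg a \code{CompartmentGraph}.
#' @param section_id section index.
#' @param arc arc position in [0, 1].
#' @return compartment index.
#' @export
locate_compartment <- function(cg, section_id, arc) {
  mapply(function(sid, a) {
    rows <- which(cg$comp$section == sid)
    if (length(rows) == 0L) stop("unknown section id: ", sid)
    rows[pmin(length(rows), findInterval(a, cg$comp$arc0[rows]))]
  }, section_id, arc)
}

#' @export
print.CompartmentGraph <- function(x, ...) {
  cat("CompartmentGraph:", nrow(x$comp), "compartments, total area",
      sprintf("%.0f um^2", total_area(x)), "\n")
  invisible(x)
}
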