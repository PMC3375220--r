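#' Attenuation-dependent synaptic scaling
#'
#' Scales each synapse's conductance by its EPSP attenuation divided by
#' the mean attenuation of all synapses: \eqn{g_i' = g_i A_i /
#' \bar{A}}. With uniform initial conductances this preserves the mean
#' conductance exactly while giving strongly attenuated (distal) synapses
#' proportionally larger conductances — a hand-imposed synaptic democracy.
#'
#' @param g conductances, pS.
#' @param attenuation per-synapse EPSP attenuations (mean must be > 0).
#' @return scaled conductances, pS.
#' @export
scale_by_attenuation <- function(g, attenuation) {
  stopifnot(length(g) == length(attenuation))
  m <- mean(attenuation)
  if (!is.finite(m) || m <= 0) stop("mean attenuation must be positive")
  g * attenuation / m
}

#' Homeostatic regulation parameters
#'
#' @param ca_target_uM target peak spine calcium, uM (47.0, the median
#'   peak calcium of the attenuation-scaled simulations).
#' @param k learning rate controlling the speed of the conductance change
#'   (0 freezes the conductances).
#' @param n_runs number of simulation runs (500 at full scale).
#' @param n_synapses synapses activated per run (240 at full scale).
#' @param g_floor_pS conductance floor (pS).
#' @param conv_tol,conv_window early-stop: maximum relative conductance
#'   change below \code{conv_tol} over the last \code{conv_window} runs.
#' @param seed integer seed.
#' @return list of class \code{HomeostasisParams}.
#' @export
homeostasis_params <- function(ca_target_uM = 47.0, k = 0.1, n_runs = 500,
                               n_synapses = 240, g_floor_pS = 0,
                               conv_tol = 0.01, conv_window = 50,
                               seed = 1L) {
  stopifnot(ca_target_uM > 0, k >= 0, n_runs >= 1, g_floor_pS >= 0)
  structure(as.list(environment()), class = "HomeostasisParams")
}

#' One homeostatic conductance update
#'
#' Multiplicative-relative rule with its fixed point at the calcium
#' target: \deqn{g' = g (1 + k ([Ca]_T - [Ca]_{peak}) / [Ca]_T)}
#' clipped at the floor. Peak calcium below target increases the AMPA
#' conductance; above target decreases it. An additive variant
#' (\code{g' = g + k_{add} ([Ca]_T - [Ca]_{peak})}) is selectable for
#' sensitivity analysis.
#'
#' @param g conductance(s), pS (>= 0).
#' @param peak_ca_uM peak spine calcium of the run, uM.
#' @param p a \code{HomeostasisParams}.
#' @param variant \code{"multiplicative"} (default) or \code{"additive"}.
#' @param k_add_pS_per_uM additive-variant gain.
#' @return updated conductance(s), pS.
#' @export
homeostatic_update <- function(g, peak_ca_uM, p = homeostasis_params(),
                               variant = c("multiplicative", "additive"),
                               k_add_pS_per_uM = 1) {
  variant <- match.arg(variant)
  stopifnot(all(g >= 0), all(peak_ca_uM >= 0))
  gn <- if (variant == "multiplicative") {
    g * (1 + p$k * (p$ca_target_uM - peak_ca_uM) / p$ca_target_uM)
  } else {
    g + k_add_pS_per_uM * (p$ca_target_uM - peak_ca_uM)
  }
  pmax(p$g_floor_pS, gn)
}

#' Run the homeostatic peak-calcium learning loop
#'
#' Starting from uniform AMPA conductances, each run activates a fresh
#' random subset of synapses; the conductance of every activated synapse
#' is then updated from its peak calcium in that run (sub- and
#' suprathreshold responses both update). Stops at \code{p$n_runs} or on
#' convergence.
#'
#' @param cell a \code{Cell} (its current conductances are the initial
#'   state; the study starts uniform at 200 pS).
#' @param p a \code{HomeostasisParams}.
#' @param duration_ms,dt_ms,t0_ms episode settings.
#' @param trajectory_every store the full conductance vector every this
#'   many runs (1 = every run).
#' @return list of class \code{HomeostasisResult}: \code{cell} (with final
#'   conductances), \code{g_final_pS}, \code{trajectory} (data.frame run x
#'   spine with g and peak calcium), \code{n_runs_done},
#'   \code{supra_frac}, \code{converged}.
#' @export
run_homeostasis <- function(cell, p = homeostasis_params(),
                            duration_ms = 150, dt_ms = 0.025, t0_ms = 20,
                            trajectory_every = 1) {
  nsp <- nrow(cell$spine)
  stopifnot(p$n_synapses <= nsp)
  g <- cell$spine$g_ampa_pS
  traj <- list()
  rel_change <- rep(NA_real_, p$n_runs)
  supra <- logical(p$n_runs)
  done <- p$n_runs
  converged <- FALSE
  for (r in seq_len(p$n_runs)) {
    sch <- make_schedule("synchronous_supra", population = cell$spine$spine,
                         n_synapses = p$n_synapses, t0_ms = t0_ms,
                         seed = p$seed + r)
    cell <- set_spine_conductances(cell, g)
    rec <- run_episode(cell, sch, duration_ms = duration_ms, dt_ms = dt_ms,
                       record_spines = FALSE)
    supra[r] <- rec$suprathreshold
    idx <- match(sch$active, cell$spine$spine)
    peak_ca_uM <- (rec$spine_peak_ca[idx] - cell$caspine$ca0_mM) * 1e3
    g_old <- g
    g[idx] <- homeostatic_update(g[idx], peak_ca_uM, p)
    rel_change[r] <- max(abs(g - g_old) / pmax(g_old, 1e-9))
    if (r %% trajectory_every == 0) {
      traj[[length(traj) + 1]] <- data.frame(
        run = r, spine = cell$spine$spine, g_pS = g,
        peak_ca_uM = {
          z <- rep(NA_real_, nsp); z[idx] <- peak_ca_uM; z
        })
    }
    if (r >= p$conv_window &&
        all(rel_change[(r - p$conv_window + 1):r] < p$conv_tol)) {
      converged <- TRUE
      done <- r
      break
    }
  }
  cell <- set_spine_conductances(cell, g)
  structure(list(cell = cell, g_final_pS = g,
                 trajectory = do.call(rbind, traj), n_runs_done = done,
                 supra_frac = mean(supra[seq_len(done)]),
                 converged = converged, params = p),
            class = "HomeostasisResult")
}

#' Distance-dependence of somatic EPSPs (democracy report)
#'
#' Linear fit of somatic EPSP amplitude against path distance. Synaptic
#' democracy is the collapse of both the slope magnitude and the R^2
#' relative to the uniform-conductance baseline. Spines whose conductance
#' collapsed to (near) zero strength are reported separately as a
#' fraction of the total, since they produce no meaningful EPSP.
#'
#' @param epsp_soma_mV somatic EPSP amplitude per spine, mV.
#' @param path_dist path distance per spine, um.
#' @param g_pS optional conductances used to flag zero-strength spines.
#' @param zero_tol_pS conductance below which a spine counts as collapsed.
#' @return list: \code{slope_mV_per_um}, \code{r_squared},
#'   \code{intercept_mV}, \code{n}, \code{zero_fraction} (NA when g_pS is
#'   missing).
#' @export
democracy_index <- function(epsp_soma_mV, path_dist, g_pS = NULL,
                            zero_tol_pS = 1) {
  stopifnot(length(epsp_soma_mV) == length(path_dist))
  if (length(epsp_soma_mV) < 10) stop("need at least 10 spines")
  zero_frac <- NA_real_
  keep <- rep(TRUE, length(epsp_soma_mV))
  if (!is.null(g_pS)) {
    collapsed <- g_pS <= zero_tol_pS
    zero_frac <- mean(collapsed)
    keep <- !collapsed
  }
  lf <- lm(epsp_soma_mV[keep] ~ path_dist[keep])
  list(slope_mV_per_um = coef(lf)[[2]], intercept_mV = coef(lf)[[1]],
       r_squared = summary(lf)$r.squared, n = sum(keep),
       zero_fraction = zero_frac)
}
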