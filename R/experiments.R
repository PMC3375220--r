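#' Default desk-scale synthetic cell
#'
#' Convenience constructor used by the examples, tests and the acceptance
#' script: synthetic CA1-like morphology, shipped backbone profile, spines
#' placed in the stratum radiatum band. The desk profile (300 spines, 10 um
#' compartments) keeps end-to-end runs in the minutes range; the full
#' profile mirrors the study scale (600 spines).
#'
#' @param seed integer seed for morphology generation and spine placement.
#' @param n_spines number of spines (default 300 desk scale).
#' @param g_ampa_pS initial AMPA conductance, pS.
#' @param rtype_gbar_pS R-type maximal conductance, pS (0 removes the
#'   channel).
#' @param max_seg_len spatial discretization, um.
#' @param backbone a \code{BackboneConfig}; default the shipped profile.
#' @return a \code{Cell}.
#' @export
default_synthetic_cell <- function(seed = 1L, n_spines = 300,
                                   g_ampa_pS = 200, rtype_gbar_pS = 170,
                                   max_seg_len = 10,
                                   backbone = load_backbone_config()) {
  morph <- generate_ca1_morphology(morph_gen_params(seed = seed))
  spines <- place_spines(morph, n = n_spines, seed = seed + 1000L)
  build_cell(morph, backbone, spines, g_ampa_pS = g_ampa_pS,
             rtype = rtype_params(gbar_pS = rtype_gbar_pS),
             max_seg_len = max_seg_len)
}

#' Experiment configuration
#'
#' @param condition one of \code{"fig1_somatic"}, \code{"fig2_supra_sync"},
#'   \code{"fig4_async"}, \code{"fig4_subthreshold"}, \code{"fig7_scaled"},
#'   \code{"fig8_homeostasis"}, \code{"s1_paradigms"},
#'   \code{"s2_double_ampa"}, \code{"s3_no_rtype"} (named for the
#'   stimulation scenario each reproduces: somatic BAP; synchronous /
#'   asynchronous / subthreshold synaptic drive; attenuation-scaled
#'   synapses; homeostatic learning; induction-paradigm comparison;
#'   doubled AMPA; no R-type).
#' @param swc_path optional SWC morphology; NULL uses the synthetic
#'   generator.
#' @param profile \code{"desk"} (default: 300 spines, 20 episodes,
#'   240/190 activated) or \code{"full"} (600 spines, 100 episodes,
#'   240/190 activated; hours of runtime).
#' @param n_episodes,n_spines,n_supra,n_sub overrides of the profile.
#' @param seed integer seed.
#' @param min_activations analysis inclusion threshold.
#' @param out_dir optional output directory for CSV/JSON results.
#' @return list of class \code{ExperimentConfig}.
#' @export
experiment_config <- function(condition, swc_path = NULL,
                              profile = c("desk", "full"),
                              n_episodes = NULL, n_spines = NULL,
                              n_supra = NULL, n_sub = NULL, seed = 1L,
                              min_activations = 10, out_dir = NULL) {
  profile <- match.arg(profile)
  conditions <- c("fig1_somatic", "fig2_supra_sync", "fig4_async",
                  "fig4_subthreshold", "fig7_scaled", "fig8_homeostasis",
                  "s1_paradigms", "s2_double_ampa", "s3_no_rtype")
  stopifnot(condition %in% conditions)
  def <- if (profile == "desk") {
    list(n_episodes = 20, n_spines = 300, n_supra = 240, n_sub = 190)
  } else {
    list(n_episodes = 100, n_spines = 600, n_supra = 240, n_sub = 190)
  }
  structure(list(condition = condition, swc_path = swc_path,
                 profile = profile,
                 n_episodes = n_episodes %||% def$n_episodes,
                 n_spines = n_spines %||% def$n_spines,
                 n_supra = n_supra %||% def$n_supra,
                 n_sub = n_sub %||% def$n_sub, seed = seed,
                 min_activations = min_activations, out_dir = out_dir),
            class = "ExperimentConfig")
}

#' Run one experiment condition end-to-end
#'
#' Builds the cell, runs the condition's protocol, extracts per-spine
#' features, fits the signed-R^2 grid, and (for the scaling/homeostasis
#' conditions) runs the plasticity stage. Deterministic given the seed.
#' When \code{cfg$out_dir} is set, feature and fit tables are written as
#' CSV and a run summary as JSON.
#'
#' @param cfg an \code{ExperimentConfig}.
#' @return a result bundle (list); contents depend on the condition but
#'   always include \code{config} and, where applicable, \code{features}
#'   (per-spine table) and \code{grid} (signed-R^2 table).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  g_ampa <- if (cfg$condition == "s2_double_ampa") 400 else 200
  rgbar <- if (cfg$condition == "s3_no_rtype") 0 else 170
  cell <- if (is.null(cfg$swc_path)) {
    default_synthetic_cell(seed = cfg$seed, n_spines = cfg$n_spines,
                           g_ampa_pS = g_ampa, rtype_gbar_pS = rgbar)
  } else {
    morph <- read_swc(cfg$swc_path)
    spines <- place_spines(morph, n = cfg$n_spines, seed = cfg$seed + 1000L)
    build_cell(morph, load_backbone_config(), spines, g_ampa_pS = g_ampa,
               rtype = rtype_params(gbar_pS = rgbar))
  }
  out <- switch(
    cfg$condition,
    fig1_somatic = run_somatic_bap(cell, cfg),
    fig2_supra_sync = run_feature_condition(cell, cfg, "synchronous_supra",
                                            cfg$n_supra),
    s2_double_ampa = run_feature_condition(cell, cfg, "synchronous_supra",
                                           cfg$n_supra),
    s3_no_rtype = run_feature_condition(cell, cfg, "synchronous_supra",
                                        cfg$n_supra),
    fig4_async = run_feature_condition(cell, cfg, "asynchronous_supra",
                                       cfg$n_supra),
    fig4_subthreshold = run_feature_condition(cell, cfg, "subthreshold",
                                              cfg$n_sub),
    fig7_scaled = run_scaled_condition(cell, cfg),
    fig8_homeostasis = run_homeostasis_condition(cell, cfg),
    s1_paradigms = run_paradigm_comparison(cell, cfg))
  out$config <- cfg
  if (!is.null(cfg$out_dir)) write_bundle(out, cfg)
  out
}

run_somatic_bap <- function(cell, cfg, amp_nA = NULL) {
  amp <- amp_nA %||% find_rheobase(cell)
  sch <- make_schedule("somatic_injection", population = cell$spine$spine,
                       soma_amp_nA = amp, t0_ms = 20, soma_dur_ms = 50)
  trunk <- which(cell$cg$comp$region == "apical_trunk")
  rec <- run_episode(cell, sch, duration_ms = 120,
                     record_comp = c(cell$soma_comp, trunk))
  trunk_profile <- data.frame(
    path_dist = cell$cg$comp$path_dist[trunk],
    peak_v = rec$comp_peak_v[trunk],
    peak_ca_uM = (rec$comp_peak_ca[trunk] - cell$shaft_ca$ca0_mM) * 1e3)
  spine_profile <- data.frame(
    spine = cell$spine$spine, path_dist = cell$spine$path_dist,
    region = cell$spine$region,
    peak_v = rec$spine_peak_v - cell$v_init_mV,
    peak_ca_uM = (rec$spine_peak_ca - cell$caspine$ca0_mM) * 1e3)
  list(recording = rec, amp_nA = amp, trunk_profile = trunk_profile,
       spine_profile = spine_profile, ap_detected = rec$ap_detected)
}

#' Smallest 50 ms somatic current step that elicits an action potential
#'
#' Bisects the pulse amplitude until exactly one AP is triggered (the
#' somatic-injection protocol auto-tunes its amplitude with this).
#'
#' @param cell a \code{Cell}.
#' @param lo_nA,hi_nA bracketing amplitudes.
#' @param tol_nA bisection tolerance.
#' @return amplitude in nA (slightly above threshold).
#' @export
find_rheobase <- function(cell, lo_nA = 0.05, hi_nA = 4, tol_nA = 0.05) {
  fires <- function(a) {
    sch <- make_schedule("somatic_injection",
                         population = cell$spine$spine, soma_amp_nA = a,
                         t0_ms = 10, soma_dur_ms = 50)
    rec <- run_episode(cell, sch, duration_ms = 80, record_spines = FALSE)
    rec$ap_detected
  }
  if (!fires(hi_nA)) return(hi_nA)
  while (hi_nA - lo_nA > tol_nA) {
    mid <- (lo_nA + hi_nA) / 2
    if (fires(mid)) hi_nA <- mid else lo_nA <- mid
  }
  hi_nA
}

run_feature_condition <- function(cell, cfg, kind, n_syn) {
  cond <- run_condition(cell, kind = kind, n_episodes = cfg$n_episodes,
                        n_synapses = n_syn, seed = cfg$seed)
  tab <- aggregate_features(cond$features, cell$spine,
                            min_activations = cfg$min_activations)
  grid <- signed_r2_grid(tab)
  list(condition_result = cond, features = tab, grid = grid,
       supra_frac = cond$supra_frac)
}

run_scaled_condition <- function(cell, cfg) {
  probes <- probe_epsp(cell)
  ok <- is.finite(probes$attenuation)
  g_scaled <- cell$spine$g_ampa_pS
  g_scaled[ok] <- scale_by_attenuation(cell$spine$g_ampa_pS[ok],
                                       probes$attenuation[ok])
  cell_scaled <- set_spine_conductances(cell, g_scaled)
  base <- run_feature_condition(cell, cfg, "synchronous_supra", cfg$n_supra)
  scaled <- run_feature_condition(cell_scaled, cfg, "synchronous_supra",
                                  cfg$n_supra)
  ks <- compare_distributions(base$features$peak_ca, scaled$features$peak_ca)
  list(probes = probes, g_scaled_pS = g_scaled, unscaled = base,
       scaled = scaled, features = scaled$features, grid = scaled$grid,
       ks_peak_ca = ks,
       peak_ca_median_uM = median(scaled$features$peak_ca))
}

run_homeostasis_condition <- function(cell, cfg, n_runs = NULL,
                                      probe_every = NULL) {
  p <- homeostasis_params(n_runs = n_runs %||%
                            (if (cfg$profile == "desk") 200 else 500),
                          n_synapses = cfg$n_supra, seed = cfg$seed)
  probe_every <- probe_every %||% (if (cfg$profile == "desk") 3L else 1L)
  probe_ids <- cell$spine$spine[seq(1, nrow(cell$spine), by = probe_every)]
  pre <- probe_epsp(cell, probe_ids)
  hres <- run_homeostasis(cell, p, duration_ms = 100)
  post <- probe_epsp(hres$cell, probe_ids)
  gsub <- hres$g_final_pS[match(probe_ids, cell$spine$spine)]
  dem_pre <- democracy_index(pre$epsp_soma_mV, pre$path_dist)
  dem_post <- democracy_index(post$epsp_soma_mV, post$path_dist,
                              g_pS = gsub)
  list(homeostasis = hres, probes_pre = pre, probes_post = post,
       democracy_pre = dem_pre, democracy_post = dem_post,
       slope_reduction = 1 - abs(dem_post$slope_mV_per_um) /
         abs(dem_pre$slope_mV_per_um))
}

run_paradigm_comparison <- function(cell, cfg, n_sparse = 10) {
  amp <- find_rheobase(cell)
  # matched spines: one sparse subset used across paradigms
  sch_sparse <- make_schedule("somatic_plus_synapses",
                              population = cell$spine$spine,
                              n_synapses = n_sparse, t0_ms = 20,
                              soma_amp_nA = 1.5 * amp, soma_dur_ms = 5,
                              seed = cfg$seed)
  watched <- sch_sparse$active
  rec_somatic <- run_episode(cell, make_schedule(
    "somatic_injection", population = cell$spine$spine, soma_amp_nA = amp,
    t0_ms = 20, soma_dur_ms = 50), duration_ms = 150)
  rec_combo <- run_episode(cell, sch_sparse, duration_ms = 150)
  sch_full <- make_schedule("synchronous_supra",
                            population = cell$spine$spine,
                            n_synapses = cfg$n_supra, t0_ms = 20,
                            seed = cfg$seed)
  # ensure the watched spines are among the activated set
  extra <- setdiff(watched, sch_full$active)
  if (length(extra) > 0) {
    sch_full$active <- sort(c(sch_full$active[seq_len(
      length(sch_full$active) - length(extra))], extra))
    sch_full$times_ms <- rep(sch_full$t0_ms, length(sch_full$active))
  }
  rec_full <- run_episode(cell, sch_full, duration_ms = 150)
  idx <- match(watched, cell$spine$spine)
  peak <- function(rec) (rec$spine_peak_ca[idx] - cell$caspine$ca0_mM) * 1e3
  list(watched_spines = watched,
       peak_ca_uM = data.frame(spine = watched,
                               somatic = peak(rec_somatic),
                               somatic_plus_synapses = peak(rec_combo),
                               synaptic = peak(rec_full)),
       epsp_ap_delay_ms = rec_combo$ap_time - 20)
}

write_bundle <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(condition = cfg$condition, profile = cfg$profile,
                seed = cfg$seed, n_episodes = cfg$n_episodes,
                n_spines = cfg$n_spines,
                package_version = as.character(utils::packageVersion("spinescale")))
  jsonlite::write_json(stamp, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(out$features)) {
    write.csv(out$features, file.path(cfg$out_dir, "features.csv"),
              row.names = FALSE)
  }
  if (!is.null(out$grid)) {
    write.csv(out$grid, file.path(cfg$out_dir, "signed_r2_grid.csv"),
              row.names = FALSE)
  }
  invisible(cfg$out_dir)
}
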