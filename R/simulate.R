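#' Build a stimulation schedule
#'
#' Protocols follow the stimulation paradigms of the study:
#' \describe{
#'   \item{synchronous_supra}{n synapses (240 at full scale) activated at
#'     the same instant; enough to trigger a somatic AP and hence a BAP.}
#'   \item{asynchronous_supra}{same, with activation times drawn i.i.d.
#'     uniformly from a 10 ms jitter window (sharp-wave/theta-like).}
#'   \item{subthreshold}{fewer synapses (190 at full scale) activated
#'     synchronously; no somatic AP.}
#'   \item{somatic_injection}{no synapses; a 50 ms somatic current pulse
#'     elicits the AP (the classical experimental BAP paradigm).}
#'   \item{somatic_plus_synapses}{sparse synaptic activation followed by a
#'     somatic current injection 13 ms later (uncaging-style paradigm).}
#' }
#' Each synapse is activated at most once per episode. The activated
#' subset is sampled uniformly without replacement, reproducibly under
#' \code{seed}.
#'
#' @param kind protocol kind (see above).
#' @param population spine ids available (integer vector).
#' @param n_synapses number of synapses to activate.
#' @param t0_ms stimulation onset, ms.
#' @param jitter_ms width of the asynchronous jitter window, ms.
#' @param seed integer RNG seed.
#' @param soma_amp_nA,soma_onset_ms,soma_dur_ms somatic current pulse for
#'   the injection protocols (onset defaults: \code{t0_ms} for
#'   somatic_injection, \code{t0_ms} + 13 for somatic_plus_synapses).
#' @return a list of class \code{StimulusSchedule} with \code{active}
#'   (spine ids), \code{times_ms} (activation time per active spine) and
#'   \code{iclamp}.
#' @export
make_schedule <- function(kind = c("synchronous_supra", "asynchronous_supra",
                                   "subthreshold", "somatic_injection",
                                   "somatic_plus_synapses"),
                          population, n_synapses = 0, t0_ms = 20,
                          jitter_ms = 10, seed = 1L, soma_amp_nA = 1.5,
                          soma_onset_ms = NULL, soma_dur_ms = 50) {
  kind <- match.arg(kind)
  if (kind != "somatic_injection" && n_synapses > length(population)) {
    stop("n_synapses exceeds the spine population size")
  }
  active <- integer(0); times <- numeric(0)
  if (kind != "somatic_injection" && n_synapses > 0) {
    withr_seed(seed, {
      active <- sort(sample(population, n_synapses))
      times <- if (kind == "asynchronous_supra")
        t0_ms + runif(n_synapses, 0, jitter_ms)
      else rep(t0_ms, n_synapses)
    })
  }
  iclamp <- NULL
  if (kind %in% c("somatic_injection", "somatic_plus_synapses")) {
    onset <- soma_onset_ms %||%
      (if (kind == "somatic_plus_synapses") t0_ms + 13 else t0_ms)
    iclamp <- list(amp_nA = soma_amp_nA, onset_ms = onset,
                   dur_ms = soma_dur_ms)
  }
  structure(list(kind = kind, active = active, times_ms = times,
                 t0_ms = t0_ms, jitter_ms = jitter_ms, seed = seed,
                 iclamp = iclamp),
            class = "StimulusSchedule")
}

#' Integrate one stimulation episode
#'
#' Advances the coupled cable/gating/calcium system and returns uniformly
#' sampled recordings: voltage and calcium at every spine head, voltage at
#' the soma and at requested shaft compartments, plus per-spine peak
#' statistics tracked at full temporal resolution and somatic
#' action-potential detection (threshold crossing; the episode is labelled
#' supra- or subthreshold accordingly).
#'
#' @param cell a \code{Cell}.
#' @param schedule a \code{StimulusSchedule}.
#' @param duration_ms episode duration.
#' @param dt_ms integration step (default 0.025 ms).
#' @param record_dt_ms sampling interval of the returned traces.
#' @param record_comp compartment indices to record (default: soma).
#' @param record_spines record V and Ca traces for all spine heads.
#' @return list of class \code{EpisodeRecording}.
#' @export
run_episode <- function(cell, schedule, duration_ms = 150, dt_ms = 0.025,
                        record_dt_ms = 0.2, record_comp = NULL,
                        record_spines = TRUE, init_state = NULL) {
  stopifnot(inherits(cell, "Cell"), inherits(schedule, "StimulusSchedule"))
  if (is.null(init_state)) init_state <- cell$rest_state
  nsp <- nrow(cell$spine)
  act <- rep(-1, nsp)
  if (length(schedule$active) > 0) {
    idx <- match(schedule$active, cell$spine$spine)
    if (anyNA(idx)) stop("schedule refers to unknown spine ids")
    act[idx] <- schedule$times_ms
  }
  model <- list(
    parent = cell$parent0, g_axial_uS = cell$g_axial_uS, cm_nF = cell$cm_nF,
    g_pas_uS = cell$g_pas_uS, e_pas_mV = cell$e_pas_mV,
    temp_K = cell$temp_K, mechanisms = cell$mechanisms,
    shaft_ca = c(cell$shaft_ca), ca_e_mM = cell$ca_e_mM,
    spines = list(
      head_comp = as.integer(cell$spine$head_comp - 1L),
      g_ampa_pS = cell$spine$g_ampa_pS,
      g_nmda_pS = rep(cell$nmda$g_nmda_pS, nsp),
      g_car_pS = rep(cell$rtype$gbar_pS, nsp),
      act_time = act,
      head_vol_um3 = rep(cell$geom$head_volume_um3, nsp),
      nmda = list(tau1 = cell$nmda$tau1, tau2 = cell$nmda$tau2,
                  tau3 = cell$nmda$tau3, a = cell$nmda$a,
                  norm = cell$nmda$norm, e_rev_mV = cell$nmda$e_rev_mV,
                  mg_ratio = cell$nmda$mg_mM / cell$nmda$mg_k0_mM,
                  mg_slope = 2 * cell$nmda$mg_delta / rt_over_f_mv(cell$temp_K),
                  ca_perm_ratio = cell$nmda$ca_perm_ratio),
      ampa = list(tau_rise_ms = cell$ampa$tau_rise_ms,
                  tau_decay_ms = cell$ampa$tau_decay_ms,
                  norm = 1 / (exp(-dexp_peak_time(cell$ampa$tau_rise_ms,
                                                  cell$ampa$tau_decay_ms) /
                                    cell$ampa$tau_decay_ms) -
                              exp(-dexp_peak_time(cell$ampa$tau_rise_ms,
                                                  cell$ampa$tau_decay_ms) /
                                    cell$ampa$tau_rise_ms)),
                  e_rev_mV = cell$ampa$e_rev_mV,
                  ca_fraction = cell$ampa$ca_fraction),
      rtype = list(gates = cell$rtype_gates_def),
      calcium = list(ca0_mM = cell$caspine$ca0_mM,
                     tau_ca_ms = cell$caspine$tau_ca_ms,
                     kappa = cell$caspine$kappa)))
  ic <- schedule$iclamp
  stim <- list(
    iclamp_comp = if (is.null(ic)) numeric(0) else as.numeric(cell$soma_comp),
    iclamp_amp_nA = if (is.null(ic)) numeric(0) else ic$amp_nA,
    iclamp_onset_ms = if (is.null(ic)) numeric(0) else ic$onset_ms,
    iclamp_dur_ms = if (is.null(ic)) numeric(0) else ic$dur_ms)
  control <- list(
    dt_ms = dt_ms, duration_ms = duration_ms, v_init_mV = cell$v_init_mV,
    record_dt_ms = record_dt_ms,
    record_comp = as.integer(record_comp %||% cell$soma_comp),
    record_spines = record_spines, soma_comp = as.integer(cell$soma_comp),
    ap_threshold_mV = cell$ap_threshold_mV, init_state = init_state)
  out <- .engine_run(model, stim, control)
  out$schedule <- schedule
  out$suprathreshold <- isTRUE(out$ap_detected)
  class(out) <- "EpisodeRecording"
  out
}

#' Settle a cell to its resting steady state
#'
#' Integrates the unstimulated cell for \code{settle_ms} and stores the
#' final state (voltages, gates, calcium pools) in the returned cell, so
#' that every subsequent episode starts from true rest instead of the
#' nominal initialization voltage. The rest state does not depend on the
#' AMPA conductances (synapses are shut at rest), so it remains valid
#' across conductance updates.
#'
#' @param cell a \code{Cell}.
#' @param settle_ms settling time, ms.
#' @param dt_ms integration step.
#' @return the cell with a \code{rest_state} field.
#' @export
equilibrate <- function(cell, settle_ms = 500, dt_ms = 0.05) {
  sch <- structure(list(kind = "rest", active = integer(0),
                        times_ms = numeric(0), t0_ms = 0, jitter_ms = 0,
                        seed = 0L, iclamp = NULL),
                   class = "StimulusSchedule")
  cell$rest_state <- NULL
  rec <- run_episode(cell, sch, duration_ms = settle_ms, dt_ms = dt_ms,
                     record_dt_ms = settle_ms / 2, record_spines = FALSE)
  cell$rest_state <- rec$final_state
  cell
}

#' Repeat a stimulation condition over independent episodes
#'
#' Repeats \code{run_episode} with a fresh activated subset (and jitter)
#' each episode, matching the repeated-simulation design of the study:
#' the spine population is fixed, the activated subset is redrawn. Returns
#' per-episode, per-activated-spine signal features plus per-spine
#' activation counts.
#'
#' @param cell a \code{Cell}.
#' @param kind protocol kind (see \code{\link{make_schedule}}).
#' @param n_episodes number of episodes (100 at full scale).
#' @param n_synapses activated synapses per episode.
#' @param seed integer seed; episode e uses \code{seed + e}.
#' @param t0_ms,jitter_ms,duration_ms,dt_ms,record_dt_ms forwarded.
#' @param integral_window_ms feature integration window after stimulation.
#' @param baseline_ms baseline window before stimulation.
#' @return list of class \code{ConditionResult} with \code{features}
#'   (data.frame: episode, spine, act_time, supra, peak/integral/delay for
#'   V and Ca), \code{counts} (activation count per spine),
#'   \code{n_episodes}, \code{supra_frac}.
#' @export
run_condition <- function(cell, kind = "synchronous_supra", n_episodes = 20,
                          n_synapses = 120, seed = 1L, t0_ms = 20,
                          jitter_ms = 10, duration_ms = 150, dt_ms = 0.025,
                          record_dt_ms = 0.2, integral_window_ms = 300,
                          baseline_ms = 20) {
  feats <- vector("list", n_episodes)
  counts <- setNames(rep(0L, nrow(cell$spine)), cell$spine$spine)
  supra <- logical(n_episodes)
  for (e in seq_len(n_episodes)) {
    sch <- make_schedule(kind, population = cell$spine$spine,
                         n_synapses = n_synapses, t0_ms = t0_ms,
                         jitter_ms = jitter_ms, seed = seed + e)
    rec <- run_episode(cell, sch, duration_ms = duration_ms, dt_ms = dt_ms,
                       record_dt_ms = record_dt_ms, record_spines = TRUE)
    supra[e] <- rec$suprathreshold
    f <- episode_features(cell, rec, integral_window_ms = integral_window_ms,
                          baseline_ms = baseline_ms)
    f$episode <- e
    feats[[e]] <- f
    counts[as.character(f$spine)] <- counts[as.character(f$spine)] + 1L
  }
  structure(list(features = do.call(rbind, feats), counts = counts,
                 n_episodes = n_episodes, supra = supra,
                 supra_frac = mean(supra), kind = kind, seed = seed),
            class = "ConditionResult")
}

#' Per-activated-spine signal features of one episode
#'
#' For every spine activated in the episode: peak (baseline-subtracted
#' maximum after its own activation time), integral (trapezoidal area over
#' the analysis window) and delay-to-peak (time from synapse stimulation
#' to the peak) of the spine-head voltage and calcium traces.
#'
#' @param cell a \code{Cell}.
#' @param rec an \code{EpisodeRecording} with spine traces.
#' @param integral_window_ms analysis window length after activation.
#' @param baseline_ms pre-stimulus window for the baseline mean.
#' @return data.frame with one row per activated spine.
#' @export
episode_features <- function(cell, rec, integral_window_ms = 300,
                             baseline_ms = 20) {
  sch <- rec$schedule
  if (length(sch$active) == 0) {
    return(data.frame(spine = integer(), act_time = numeric(),
                      supra = logical(), peak_v = numeric(),
                      int_v = numeric(), delay_v = numeric(),
                      peak_ca = numeric(), int_ca = numeric(),
                      delay_ca = numeric()))
  }
  idx <- match(sch$active, cell$spine$spine)
  t <- rec$t
  out <- lapply(seq_along(idx), function(j) {
    s <- idx[j]
    ts <- sch$times_ms[j]
    fv <- extract_features(t, rec$spine_v[, s], stim_time = ts,
                           window_ms = integral_window_ms,
                           baseline_ms = baseline_ms)
    fc <- extract_features(t, rec$spine_ca[, s] * 1e3, stim_time = ts,
                           window_ms = integral_window_ms,
                           baseline_ms = baseline_ms)   # uM
    data.frame(spine = sch$active[j], act_time = ts,
               supra = rec$suprathreshold,
               peak_v = fv$peak, int_v = fv$integral, delay_v = fv$delay,
               peak_ca = fc$peak, int_ca = fc$integral, delay_ca = fc$delay)
  })
  do.call(rbind, out)
}

#' Somatic EPSP amplitude and attenuation probes
#'
#' Runs one dedicated single-synapse subthreshold episode per requested
#' spine: only that synapse is activated, and the baseline-subtracted EPSP
#' peaks at the spine head and at the soma are measured. These probes feed
#' \code{\link{compute_attenuation}} and \code{\link{democracy_index}}.
#'
#' @param cell a \code{Cell}.
#' @param spine_ids spines to probe (default all).
#' @param duration_ms probe episode duration.
#' @param dt_ms integration step.
#' @param t0_ms activation time.
#' @return data.frame: spine, path_dist, epsp_spine_mV, epsp_soma_mV,
#'   attenuation.
#' @export
probe_epsp <- function(cell, spine_ids = cell$spine$spine,
                       duration_ms = 80, dt_ms = 0.025, t0_ms = 10) {
  rows <- lapply(spine_ids, function(sid) {
    sch <- structure(list(kind = "probe", active = sid, times_ms = t0_ms,
                          t0_ms = t0_ms, jitter_ms = 0, seed = 0L,
                          iclamp = NULL), class = "StimulusSchedule")
    rec <- run_episode(cell, sch, duration_ms = duration_ms, dt_ms = dt_ms,
                       record_dt_ms = 0.1, record_spines = TRUE)
    s <- match(sid, cell$spine$spine)
    pre <- rec$t < t0_ms
    v_sp <- rec$spine_v[, s]
    v_soma <- rec$soma_v
    epsp_sp <- max(v_sp[!pre]) - mean(v_sp[pre])
    epsp_soma <- max(v_soma[!pre]) - mean(v_soma[pre])
    data.frame(spine = sid, path_dist = cell$spine$path_dist[s],
               epsp_spine_mV = epsp_sp, epsp_soma_mV = epsp_soma)
  })
  out <- do.call(rbind, rows)
  out$attenuation <- compute_attenuation(out$epsp_spine_mV, out$epsp_soma_mV)
  out
}
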