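#' Spine geometry
#'
#' Spines are modelled as two cylindrical compartments: a neck (diameter
#' 0.2 um, length 1.0 um) and a head (diameter 0.4 um, length 0.2 um).
#' The head volume enters the calcium balance.
#'
#' @param neck_diam,neck_len,head_diam,head_len dimensions in um.
#' @return list of class \code{SpineGeometry} with the dimensions and the
#'   head volume \code{head_volume_um3}.
#' @export
spine_geometry <- function(neck_diam = 0.2, neck_len = 1.0,
                           head_diam = 0.4, head_len = 0.2) {
  stopifnot(neck_diam > 0, neck_len > 0, head_diam > 0, head_len > 0)
  structure(list(neck_diam = neck_diam, neck_len = neck_len,
                 head_diam = head_diam, head_len = head_len,
                 head_volume_um3 = pi * (head_diam / 2)^2 * head_len),
            class = "SpineGeometry")
}

#' Spine calcium kinetics parameters
#'
#' First-order accumulation, buffering and extrusion of calcium in the
#' spine head: resting concentration 70 nM, extrusion time constant 12 ms,
#' buffer capacity kappa = 20, extracellular calcium 2 mM. No diffusion
#' through the spine neck.
#'
#' @param ca0_mM resting intracellular calcium, mM.
#' @param tau_ca_ms extrusion (pump) time constant, ms.
#' @param kappa dimensionless buffer capacity.
#' @param ca_e_mM extracellular calcium, mM.
#' @return list of class \code{CalciumParams}.
#' @export
calcium_params <- function(ca0_mM = 70e-6, tau_ca_ms = 12, kappa = 20,
                           ca_e_mM = 2) {
  stopifnot(ca0_mM > 0, tau_ca_ms > 0, kappa > 0, ca_e_mM > 0)
  structure(list(ca0_mM = ca0_mM, tau_ca_ms = tau_ca_ms, kappa = kappa,
                 ca_e_mM = ca_e_mM), class = "CalciumParams")
}

#' Q10 temperature scaling of a kinetic time constant
#'
#' \code{tau_measured * Q10^(-(T_sim - T_measured)/10)}. Scaling composes
#' exactly: 22 to 28 then 28 to 34 equals 22 to 34.
#'
#' @param tau_ms measured time constant, ms.
#' @param t_measured_c measurement temperature, degrees Celsius.
#' @param t_sim_c simulation temperature, degrees Celsius.
#' @param q10 Q10 factor (> 0), typically 3 for ion channel kinetics.
#' @return scaled time constant, ms.
#' @export
q10_scale <- function(tau_ms, t_measured_c, t_sim_c, q10 = 3) {
  stopifnot(q10 > 0)
  tau_ms * q10^(-(t_sim_c - t_measured_c) / 10)
}

#' NMDA receptor parameters
#'
#' Conductance time course is a sum of exponentials with one rise (1.7 ms)
#' and two decay components (68 ms, 444 ms), all measured at 22 C and by
#' default Q10-corrected (Q10 = 3) to the simulation temperature of 34 C.
#' Peak open conductance 45 pS (a 70 pS single-spine peak reduced 40% for
#' steady-state calcium-dependent inactivation). Magnesium block is an
#' instantaneous Woodhull-type sigmoid; the calcium component of the
#' current uses the GHK driving force scaled by the calcium:caesium
#' permeability ratio.
#'
#' @param tau_rise_ms,tau_decay_fast_ms,tau_decay_slow_ms time constants at
#'   \code{t_measured_c}, ms.
#' @param decay_fast_weight weight a of the fast decay component in [0, 1]
#'   (slow component weight 1 - a). Not printed in the source recordings;
#'   default 0.8.
#' @param g_nmda_pS peak open conductance, pS.
#' @param e_rev_mV reversal potential of the nonspecific current, mV.
#' @param mg_mM external magnesium concentration, mM.
#' @param mg_k0_mM Woodhull dissociation constant at 0 mV, mM.
#' @param mg_delta effective electrical depth of the magnesium binding
#'   site. Values above 1 are permitted as a phenomenological steepening:
#'   steady-state trapping-block models are steeper than a simple Woodhull
#'   barrier, and the cited block model is of the trapping type.
#' @param ca_perm_ratio calcium:caesium permeability ratio scaling the GHK
#'   calcium flux relative to the nonspecific conductance (about 10 in CA1).
#' @param t_measured_c,t_sim_c recording/simulation temperature, C.
#' @param q10 Q10 for the time constants.
#' @param apply_q10 whether the printed time constants are 22 C
#'   measurements to be corrected (default) or already at \code{t_sim_c}.
#' @return list of class \code{NMDAParams} with the simulation-temperature
#'   time constants in \code{tau1}, \code{tau2}, \code{tau3} and the peak
#'   normalization factor \code{norm}.
#' @export
nmda_params <- function(tau_rise_ms = 1.7, tau_decay_fast_ms = 68,
                        tau_decay_slow_ms = 444, decay_fast_weight = 0.8,
                        g_nmda_pS = 45, e_rev_mV = 0, mg_mM = 1,
                        mg_k0_mM = 3.57, mg_delta = 1.3, ca_perm_ratio = 6,
                        t_measured_c = 22, t_sim_c = 34, q10 = 3,
                        apply_q10 = TRUE) {
  stopifnot(tau_rise_ms < tau_decay_fast_ms,
            tau_decay_fast_ms < tau_decay_slow_ms,
            g_nmda_pS >= 0, decay_fast_weight >= 0, decay_fast_weight <= 1,
            mg_mM > 0, mg_k0_mM > 0, mg_delta > 0, mg_delta <= 1.5)
  sc <- if (apply_q10) q10_scale(1, t_measured_c, t_sim_c, q10) else 1
  p <- list(tau1 = tau_rise_ms * sc, tau2 = tau_decay_fast_ms * sc,
            tau3 = tau_decay_slow_ms * sc, a = decay_fast_weight,
            g_nmda_pS = g_nmda_pS, e_rev_mV = e_rev_mV, mg_mM = mg_mM,
            mg_k0_mM = mg_k0_mM, mg_delta = mg_delta,
            ca_perm_ratio = ca_perm_ratio,
            temp_K = celsius_to_kelvin(t_sim_c))
  p$norm <- 1 / nmda_shape_max(p)
  class(p) <- "NMDAParams"
  p
}

nmda_shape <- function(t, p) {
  ifelse(t <= 0, 0,
         p$a * exp(-t / p$tau2) + (1 - p$a) * exp(-t / p$tau3) -
           exp(-t / p$tau1))
}

nmda_shape_max <- function(p) {
  optimize(function(t) nmda_shape(t, p), c(0, 20 * p$tau1 + p$tau2),
           maximum = TRUE)$objective
}

#' Fraction of NMDA channels unblocked by magnesium
#'
#' Instantaneous, voltage-dependent relief of the magnesium block,
#' modelled as a Woodhull-type sigmoid:
#' \deqn{B(V) = 1 / (1 + ([Mg]/K_0) \exp(-2\delta F V / (R T)))}
#' strictly increasing in V, approaching 1 at large depolarization and 0 at
#' large hyperpolarization. With the defaults (K0 = 3.57 mM, delta = 1.3,
#' 1 mM Mg, 34 C) the exponent is about 0.098/mV (e-fold per ~10 mV),
#' steeper than the classic empirical fit, consistent with the
#' steady-state behaviour of trapping-block models.
#'
#' @param v_mV membrane potential, mV.
#' @param p an \code{NMDAParams} object.
#' @return fraction in (0, 1).
#' @export
mg_unblock_fraction <- function(v_mV, p = nmda_params()) {
  slope <- 2 * p$mg_delta / rt_over_f_mv(p$temp_K)   # per mV
  1 / (1 + (p$mg_mM / p$mg_k0_mM) * exp(-slope * v_mV))
}

#' Effective calcium driving force from the GHK current equation
#'
#' The Goldman-Hodgkin-Katz flux for a divalent ion, expressed as an
#' effective driving force \eqn{V_{Ca}} (mV) such that \eqn{I_{Ca} = g
#' V_{Ca}}, normalized so that \eqn{dI/dV \to g} for large negative V
#' (g is then the slope conductance of the channel):
#' \deqn{V_{Ca}(V) = V \frac{[Ca]_i e^{\xi} - [Ca]_e}{[Ca]_e (e^{\xi}-1)},
#'  \qquad \xi = 2FV/(RT).}
#' The removable singularity at V = 0 is evaluated by its analytic limit.
#' \eqn{V_{Ca} = 0} exactly at the calcium Nernst potential, and is
#' negative (calcium influx, with inward current negative) at physiological
#' potentials when \eqn{[Ca]_e \gg [Ca]_i}.
#'
#' @param v_mV membrane potential, mV.
#' @param ca_i_mM,ca_e_mM intra/extracellular calcium, mM (> 0).
#' @param temp_K absolute temperature, K.
#' @return effective driving force, mV.
#' @export
ghk_driving_force <- function(v_mV, ca_i_mM = 70e-6, ca_e_mM = 2,
                              temp_K = celsius_to_kelvin(34)) {
  stopifnot(all(ca_i_mM > 0), all(ca_e_mM > 0))
  vt <- rt_over_f_mv(temp_K) / 2      # RT/(2F) in mV
  n <- max(length(v_mV), length(ca_i_mM), length(ca_e_mM))
  v <- rep_len(v_mV, n)
  r <- rep_len(ca_i_mM / ca_e_mM, n)
  xi <- v / vt
  small <- abs(xi) < 1e-4
  out <- numeric(n)
  # series around V = 0: vt (r - 1) + V (r + 1)/2 + O(V^2)
  out[small] <- vt * (r[small] - 1) + v[small] * (r[small] + 1) / 2
  ex <- exp(xi[!small])
  out[!small] <- v[!small] * (r[!small] * ex - 1) / (ex - 1)
  out
}

#' NMDA receptor state at a given time and voltage
#'
#' The open conductance is the peak-normalized sum-of-exponentials time
#' course multiplied by the unblocked fraction. The nonspecific current
#' uses a linear driving force (V - E); the calcium current uses the GHK
#' effective driving force scaled by the calcium:caesium permeability
#' ratio.
#'
#' @param t_ms time since synapse activation, ms (>= 0).
#' @param v_mV membrane potential, mV.
#' @param p an \code{NMDAParams} object.
#' @param ca_i_mM intracellular calcium at the receptor, mM.
#' @param ca_e_mM extracellular calcium, mM.
#' @return list with \code{g_open_pS} (unblocked open conductance),
#'   \code{i_m_pA} (nonspecific current) and \code{i_ca_pA} (calcium
#'   current); outward currents positive.
#' @export
nmda_state <- function(t_ms, v_mV, p = nmda_params(), ca_i_mM = 70e-6,
                       ca_e_mM = 2) {
  if (any(t_ms < 0)) stop("negative time since activation")
  g_time <- p$g_nmda_pS * p$norm * nmda_shape(t_ms, p)
  b <- mg_unblock_fraction(v_mV, p)
  g <- g_time * b
  vca <- ghk_driving_force(v_mV, ca_i_mM, ca_e_mM, p$temp_K)
  list(g_open_pS = g,
       i_m_pA = 1e-3 * g * (v_mV - p$e_rev_mV),
       i_ca_pA = 1e-3 * g * p$ca_perm_ratio * vca)
}

#' AMPA receptor parameters
#'
#' Dual-exponential conductance (rise 0.2 ms, decay 5 ms) peaking at
#' \code{g_ampa_pS} (200 pS for all synapses in unscaled simulations);
#' current split 99.8% nonspecific : 0.2% calcium.
#'
#' @param tau_rise_ms,tau_decay_ms time constants, ms.
#' @param g_ampa_pS peak conductance, pS.
#' @param e_rev_mV reversal potential, mV.
#' @param ca_fraction calcium fraction of the AMPA current (0.002).
#' @return list of class \code{AMPAParams}.
#' @export
ampa_params <- function(tau_rise_ms = 0.2, tau_decay_ms = 5,
                        g_ampa_pS = 200, e_rev_mV = 0, ca_fraction = 0.002) {
  stopifnot(tau_rise_ms < tau_decay_ms, g_ampa_pS >= 0,
            ca_fraction >= 0, ca_fraction <= 1)
  structure(list(tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 g_ampa_pS = g_ampa_pS, e_rev_mV = e_rev_mV,
                 ca_fraction = ca_fraction), class = "AMPAParams")
}

#' AMPA receptor state at a given time and voltage
#'
#' @param t_ms time since synapse activation, ms (>= 0).
#' @param v_mV membrane potential, mV.
#' @param p an \code{AMPAParams} object.
#' @return list with \code{g_pS}, \code{i_m_pA}, \code{i_ca_pA}; outward
#'   positive.
#' @export
ampa_state <- function(t_ms, v_mV, p = ampa_params()) {
  if (any(t_ms < 0)) stop("negative time since activation")
  g <- p$g_ampa_pS * dexp_shape(t_ms, p$tau_rise_ms, p$tau_decay_ms)
  i_tot <- 1e-3 * g * (v_mV - p$e_rev_mV)
  list(g_pS = g, i_m_pA = (1 - p$ca_fraction) * i_tot,
       i_ca_pA = p$ca_fraction * i_tot)
}

#' R-type calcium channel parameters
#'
#' High-voltage-activated calcium channel on the spine head with
#' Hodgkin-Huxley activation (m) and inactivation (h) gates. The maximal
#' conductance of 170 pS (10 channels of 17 pS unitary conductance) is the
#' slope conductance the GHK current approaches at large negative voltages.
#' Gate kinetics are Boltzmann steady states with bell-shaped time
#' constants recorded at 22 C and Q10-scaled (Q10 = 3) to 34 C. The exact
#' kinetic constants of the source recordings are not printed; the defaults
#' below are a conventional HVA parameterization and are config-exposed.
#'
#' @param gbar_pS maximal (slope) conductance per spine, pS.
#' @param m_vhalf,m_k activation steady-state Boltzmann midpoint/slope, mV.
#' @param m_power activation gate exponent.
#' @param m_tau bell-shaped time constant parameters at
#'   \code{t_measured_c}: \code{c(min, amp, vpeak, k1, k2)} giving
#'   \code{min + amp / (exp((V - vpeak)/k1) + exp(-(V - vpeak)/k2))}, ms.
#' @param h_vhalf,h_k inactivation midpoint/slope, mV (negative slope).
#' @param h_power inactivation gate exponent.
#' @param h_tau inactivation time constant parameters, same form, ms.
#' @param t_measured_c,t_sim_c,q10 temperature correction of the time
#'   constants.
#' @return list of class \code{RTypeParams}; \code{tau_scale} is the Q10
#'   factor applied to both gate time constants.
#' @export
rtype_params <- function(gbar_pS = 170, m_vhalf = -11, m_k = 8.3,
                         m_power = 2,
                         m_tau = c(0.8, 1.5, -10, 18, 18),
                         h_vhalf = -39, h_k = -9.2, h_power = 1,
                         h_tau = c(40, 80, -40, 20, 20),
                         t_measured_c = 22, t_sim_c = 34, q10 = 3) {
  stopifnot(gbar_pS >= 0, m_tau[1] > 0, h_tau[1] > 0)
  structure(list(gbar_pS = gbar_pS, m_vhalf = m_vhalf, m_k = m_k,
                 m_power = m_power, m_tau = m_tau, h_vhalf = h_vhalf,
                 h_k = h_k, h_power = h_power, h_tau = h_tau,
                 tau_scale = q10_scale(1, t_measured_c, t_sim_c, q10),
                 temp_K = celsius_to_kelvin(t_sim_c)),
            class = "RTypeParams")
}

boltzmann_inf <- function(v, vhalf, k) 1 / (1 + exp(-(v - vhalf) / k))

bell_tau <- function(v, pars, scale = 1) {
  scale * (pars[1] + pars[2] / (exp((v - pars[3]) / pars[4]) +
                                exp(-(v - pars[3]) / pars[5])))
}

#' R-type gate steady states and time constants
#'
#' @param v_mV membrane potential, mV.
#' @param p an \code{RTypeParams} object.
#' @return list with \code{m_inf}, \code{h_inf}, \code{tau_m_ms},
#'   \code{tau_h_ms} (time constants at the simulation temperature).
#' @export
rtype_gates <- function(v_mV, p = rtype_params()) {
  list(m_inf = boltzmann_inf(v_mV, p$m_vhalf, p$m_k),
       h_inf = boltzmann_inf(v_mV, p$h_vhalf, p$h_k),
       tau_m_ms = bell_tau(v_mV, p$m_tau, p$tau_scale),
       tau_h_ms = bell_tau(v_mV, p$h_tau, p$tau_scale))
}

#' R-type calcium current
#'
#' \eqn{I = \bar g \, m^{p_m} h^{p_h} \, V_{Ca}(V)} with the GHK effective
#' driving force; the numerical slope dI/dV at large negative V approaches
#' \eqn{\bar g m^{p_m} h^{p_h}}.
#'
#' @param v_mV membrane potential, mV.
#' @param m,h gate values in [0, 1].
#' @param p an \code{RTypeParams} object.
#' @param ca_i_mM,ca_e_mM intra/extracellular calcium, mM.
#' @return current in pA (outward positive; negative = calcium influx).
#' @export
rtype_current <- function(v_mV, m, h, p = rtype_params(), ca_i_mM = 70e-6,
                          ca_e_mM = 2) {
  stopifnot(all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  1e-3 * p$gbar_pS * m^p$m_power * h^p$h_power *
    ghk_driving_force(v_mV, ca_i_mM, ca_e_mM, p$temp_K)
}

#' Advance spine-head calcium by one time step
#'
#' First-order kinetics of accumulation, buffering and extrusion:
#' \deqn{d[Ca]/dt = -I_{Ca} / (2 F v \kappa) - ([Ca] - [Ca]_0)/\tau_{Ca}}
#' with inward calcium current negative (so influx raises [Ca]).
#' Integrated with the exact exponential update for a current held
#' constant over the step (unconditionally stable).
#'
#' @param ca_mM current concentration, mM (>= 0).
#' @param i_ca_pA total calcium current (NMDA + AMPA + R-type), pA.
#' @param dt_ms time step, ms (> 0).
#' @param geom a \code{SpineGeometry} (supplies the head volume).
#' @param cp a \code{CalciumParams}.
#' @return concentration after the step, mM.
#' @export
step_spine_calcium <- function(ca_mM, i_ca_pA, dt_ms,
                               geom = spine_geometry(),
                               cp = calcium_params()) {
  stopifnot(dt_ms > 0, all(ca_mM >= 0))
  influx <- ca_influx_rate(i_ca_pA, geom$head_volume_um3, cp$kappa)
  ca_inf <- cp$ca0_mM + cp$tau_ca_ms * influx
  pmax(0, ca_inf + (ca_mM - ca_inf) * exp(-dt_ms / cp$tau_ca_ms))
}

# d[Ca]/dt contribution of a calcium current, in mM/ms.
# i_pA outward positive; vol in um^3; returns -I/(2 F v kappa).
# (pA / (C/mol * L) = M/s, and 1 M/s = 1 mM/ms.)
ca_influx_rate <- function(i_pA, vol_um3, kappa) {
  -(i_pA * 1e-12) / (2 * PHYS$FARADAY * vol_um3 * PHYS$L_PER_UM3 * kappa)
}
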