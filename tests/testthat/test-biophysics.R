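test_that("q10_scale: identity, direct evaluation, symmetry, composition", {
  expect_equal(q10_scale(12, 34, 34, 3), 12)
  expect_equal(q10_scale(68, 22, 34, 3), 68 * 3^(-1.2))
  expect_equal(q10_scale(10, 34, 22, 3), 10 * 3^(1.2))
  # group action: 22->28 then 28->34 equals 22->34
  expect_equal(q10_scale(q10_scale(5, 22, 28, 3), 28, 34, 3),
               q10_scale(5, 22, 34, 3), tolerance = 1e-12)
})

test_that("mg_unblock_fraction is a saturating, strictly increasing sigmoid", {
  p <- nmda_params()
  expect_gt(mg_unblock_fraction(200, p), 0.99)
  expect_lt(mg_unblock_fraction(-200, p), 0.01)
  v <- seq(-120, 80, by = 2)
  f <- mg_unblock_fraction(v, p)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  # brute-force evaluation of the chosen block formula at two voltages
  slope <- 2 * p$mg_delta * PHYS$FARADAY /
    (1e3 * PHYS$GAS_CONSTANT * p$temp_K)
  direct <- function(v) 1 / (1 + (p$mg_mM / p$mg_k0_mM) * exp(-slope * v))
  expect_equal(mg_unblock_fraction(-70, p), direct(-70), tolerance = 1e-12)
  expect_lt(mg_unblock_fraction(-70, p), mg_unblock_fraction(0, p))
})

test_that("ghk_driving_force: reversal, V=0 limit, oracle evaluation, slope", {
  tK <- celsius_to_kelvin(34)
  # Nernst reversal for the given concentrations
  nernst <- 1e3 * PHYS$GAS_CONSTANT * tK / (2 * PHYS$FARADAY) * log(2 / 70e-6)
  expect_equal(ghk_driving_force(nernst, 70e-6, 2, tK), 0, tolerance = 1e-9)
  # removable singularity at V = 0: finite and equal to the series limit
  v0 <- ghk_driving_force(0, 70e-6, 2, tK)
  expect_true(is.finite(v0))
  vt2 <- 1e3 * PHYS$GAS_CONSTANT * tK / (2 * PHYS$FARADAY)
  expect_equal(v0, vt2 * (70e-6 / 2 - 1), tolerance = 1e-9)
  expect_equal(ghk_driving_force(1e-9, 70e-6, 2, tK), v0, tolerance = 1e-6)
  # oracle: classical GHK current expression, normalized by its numerically
  # measured slope conductance at very negative voltage
  ghk_flux <- function(v, cai, cae) {
    xi <- 2 * v * 1e-3 * PHYS$FARADAY / (PHYS$GAS_CONSTANT * tK)
    v * (cai - cae * exp(-xi)) / (1 - exp(-xi))
  }
  slope <- (ghk_flux(-1000 + 1e-4, 70e-6, 2) -
            ghk_flux(-1000 - 1e-4, 70e-6, 2)) / 2e-4
  expect_equal(ghk_driving_force(-70, 70e-6, 2, tK),
               ghk_flux(-70, 70e-6, 2) / slope, tolerance = 1e-6)
  # influx-favouring sign at rest
  expect_lt(ghk_driving_force(-70, 70e-6, 2, tK), 0)
  expect_error(ghk_driving_force(-70, -1, 2, tK))
})

test_that("nmda_state: rise from zero, peak normalization, reversal split", {
  p <- nmda_params()
  s0 <- nmda_state(0, -65, p)
  expect_equal(s0$g_open_pS, 0)
  # numeric maximization oracle: unblocked time course peaks at g_NMDA
  tt <- seq(0, 400, by = 0.01)
  g_unblocked <- p$g_nmda_pS * p$norm *
    (p$a * exp(-tt / p$tau2) + (1 - p$a) * exp(-tt / p$tau3) -
       exp(-tt / p$tau1))
  expect_equal(max(g_unblocked), p$g_nmda_pS, tolerance = 1e-6)
  # V = E_NMDA: nonspecific current zero, GHK calcium current nonzero
  sE <- nmda_state(5, p$e_rev_mV, p)
  expect_equal(sE$i_m_pA, 0)
  expect_true(sE$i_ca_pA != 0)
  expect_error(nmda_state(-1, -65, p), "negative")
})

test_that("NMDA time constants are Q10-corrected from 22 C by default", {
  p <- nmda_params()
  expect_equal(p$tau2, 68 * 3^(-1.2))
  p0 <- nmda_params(apply_q10 = FALSE)
  expect_equal(p0$tau2, 68)
})

test_that("ampa_state: onset, closed-form argmax, calcium split", {
  p <- ampa_params()
  expect_equal(ampa_state(0, -65, p)$g_pS, 0)
  # peak of normalized dual exponential at t = ln(taud/taur) taud taur/(taud-taur)
  tpk <- log(5 / 0.2) * 5 * 0.2 / (5 - 0.2)
  expect_equal(dexp_peak_time(0.2, 5), tpk)
  tt <- seq(0, 30, by = 1e-3)
  g <- ampa_state(tt, -65, p)$g_pS
  expect_equal(tt[which.max(g)], tpk, tolerance = 1e-2)
  expect_equal(max(g), p$g_ampa_pS, tolerance = 1e-6)
  # calcium fraction of the total current is 0.2% at any fixed voltage
  s <- ampa_state(1.3, -40, p)
  expect_equal(s$i_ca_pA / (s$i_ca_pA + s$i_m_pA), 0.002, tolerance = 1e-12)
})

test_that("rtype_current: gate zeros and slope-conductance property", {
  p <- rtype_params()
  expect_equal(rtype_current(-20, 0, 1, p), 0)
  expect_equal(rtype_current(-20, 0.5, 0, p), 0)
  # at large negative V the numerical dI/dV approaches gbar * m^pm * h
  m <- 0.6; h <- 0.8
  dIdV <- (rtype_current(-119.9, m, h, p) - rtype_current(-120.1, m, h, p)) /
    0.2
  expect_equal(dIdV, 1e-3 * p$gbar_pS * m^p$m_power * h, tolerance = 0.02)
  # gate steady states monotone in the expected directions
  v <- seq(-90, 40, by = 5)
  gs <- rtype_gates(v, p)
  expect_true(all(diff(gs$m_inf) > 0))
  expect_true(all(diff(gs$h_inf) < 0))
  expect_true(all(gs$tau_m_ms > 0 & gs$tau_h_ms > 0))
  expect_error(rtype_current(-20, 1.5, 0.5, p))
})

test_that("step_spine_calcium matches first-order closed forms", {
  geom <- spine_geometry(); cp <- calcium_params()
  # fixed point at rest with zero current
  expect_equal(step_spine_calcium(70e-6, 0, 0.5, geom, cp), 70e-6)
  # relaxation from 1 uM toward rest with tau = 12 ms
  ca <- 1e-3
  for (i in 1:240) ca <- step_spine_calcium(ca, 0, 0.05, geom, cp)
  expected <- cp$ca0_mM + (1e-3 - cp$ca0_mM) * exp(-12 / cp$tau_ca_ms)
  expect_equal(ca, expected, tolerance = 1e-3 * expected)
  # steady state under constant inward current
  i_ca <- -0.5   # pA inward
  ca <- cp$ca0_mM
  for (i in 1:4000) ca <- step_spine_calcium(ca, i_ca, 0.05, geom, cp)
  ca_inf <- cp$ca0_mM + cp$tau_ca_ms * 0.5e-12 /
    (2 * PHYS$FARADAY * geom$head_volume_um3 * 1e-15 * cp$kappa)
  expect_equal(ca, ca_inf, tolerance = 0.005 * ca_inf)
  expect_error(step_spine_calcium(70e-6, 0, -0.1, geom, cp))
})

test_that("spine geometry volume and calcium parameter invariants", {
  g <- spine_geometry()
  expect_equal(g$head_volume_um3, pi * 0.2^2 * 0.2)
  expect_error(spine_geometry(neck_diam = 0))
  expect_error(calcium_params(tau_ca_ms = -1))
  expect_error(nmda_params(tau_rise_ms = 100))      # tau1 < tau2 violated
  expect_error(ampa_params(tau_rise_ms = 10))
})
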