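test_that("scale_by_attenuation: identity, mean preservation, arithmetic", {
  expect_equal(scale_by_attenuation(c(200, 200, 200), c(2, 2, 2)),
               c(200, 200, 200))
  # uniform g: mean conductance preserved exactly
  set.seed(3)
  a <- runif(50, 0.5, 20)
  g <- rep(200, 50)
  expect_equal(mean(scale_by_attenuation(g, a)), 200, tolerance = 1e-12)
  expect_equal(scale_by_attenuation(c(200, 200), c(1, 3)), c(100, 300))
  expect_error(scale_by_attenuation(c(1, 2), c(0, 0)), "positive")
})

test_that("homeostatic_update: fixed point, direction, floor, k = 0", {
  p <- homeostasis_params()
  expect_equal(homeostatic_update(200, 47.0, p), 200)     # exact fixed point
  expect_gt(homeostatic_update(200, 20, p), 200)          # below target: up
  expect_lt(homeostatic_update(200, 80, p), 200)          # above target: down
  expect_equal(homeostatic_update(0, 100, p), 0)          # stays at the floor
  p0 <- homeostasis_params(k = 0)
  expect_equal(homeostatic_update(c(10, 300), c(1, 200), p0), c(10, 300))
  # additive variant shares the fixed point
  expect_equal(homeostatic_update(200, 47.0, p, variant = "additive"), 200)
  expect_error(homeostatic_update(-5, 10, p))
})

test_that("the update has a unique interior fixed point at the target", {
  p <- homeostasis_params()
  ca <- seq(1, 120, by = 0.5)
  g1 <- homeostatic_update(rep(200, length(ca)), ca, p)
  s <- sign(g1 - 200)
  crossings <- sum(diff(s[s != 0]) != 0)   # grid hits the root exactly
  expect_equal(crossings, 1L)
  expect_equal(ca[which.min(abs(g1 - 200))], 47.0, tolerance = 0.5)
})

test_that("democracy_index quantifies distance dependence", {
  set.seed(8)
  d <- runif(100, 50, 400)
  # perfectly uniform somatic EPSPs: slope 0, R^2 ~ 0
  u <- democracy_index(rep(0.2, 100) + rnorm(100, 0, 1e-9), d)
  expect_equal(u$slope_mV_per_um, 0, tolerance = 1e-6)
  expect_lt(u$r_squared, 0.1)
  # distance-dependent EPSPs: negative slope recovered
  e <- 0.4 - 0.0008 * d + rnorm(100, 0, 0.01)
  v <- democracy_index(e, d, g_pS = c(rep(0.5, 4), rep(200, 96)))
  expect_lt(v$slope_mV_per_um, 0)
  expect_equal(v$zero_fraction, 0.04)
  expect_equal(v$n, 96)
  expect_error(democracy_index(1:5, 1:5), "at least 10")
})

test_that("run_homeostasis with k = 0 never changes conductances", {
  cell <- desk_cell()
  p <- homeostasis_params(k = 0, n_runs = 2, n_synapses = 100,
                          conv_window = 99, seed = 5)
  res <- run_homeostasis(cell, p, duration_ms = 60)
  expect_equal(res$g_final_pS, cell$spine$g_ampa_pS)
  expect_equal(res$n_runs_done, 2L)
  # trajectory is recorded per run
  expect_equal(nrow(res$trajectory), 2L * nrow(cell$spine))
  # only activated spines have a recorded peak calcium
  expect_equal(sum(!is.na(res$trajectory$peak_ca_uM)), 2L * 100L)
})

test_that("homeostatic runs move activated conductances toward the target", {
  cell <- desk_cell()
  p <- homeostasis_params(n_runs = 3, n_synapses = 240, conv_window = 99,
                          seed = 31)
  res <- run_homeostasis(cell, p, duration_ms = 100)
  traj1 <- res$trajectory[res$trajectory$run == 1, ]
  act <- !is.na(traj1$peak_ca_uM)
  # direction of the first update follows the sign of the calcium error
  dg <- traj1$g_pS[act] - 200
  err <- 47.0 - traj1$peak_ca_uM[act]
  expect_true(all(sign(dg) == sign(err) | err == 0))
  expect_equal(traj1$g_pS[!act], rep(200, sum(!act)))
})
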