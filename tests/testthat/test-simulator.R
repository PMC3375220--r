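test_that("build_cell: spine bookkeeping and plain-cable case", {
  m <- straight_cable_morph(length_um = 200, step = 20)
  bb <- passive_backbone()
  cell0 <- build_cell(m, bb, spines = NULL)
  expect_equal(nrow(cell0$spine), 0L)
  expect_equal(cell0$n_comp, cell0$n_dend)
  sp <- data.frame(spine = 1:5, section = 2L, arc = seq(0.1, 0.9, by = 0.2),
                   path_dist = NA, region = "apical_trunk")
  sp$path_dist <- path_distance(m, sp$section, sp$arc)
  cell <- build_cell(m, bb, sp)
  expect_equal(cell$n_comp, cell0$n_dend + 10L)    # two compartments per spine
  expect_error(build_cell(m, bb, transform(sp, section = 99L)),
               "unknown section")
})

test_that("passive single compartment matches the RC charging curve", {
  # point soma only: one compartment; Rm 20 kOhm cm2, Cm 1 uF/cm2 -> tau 20 ms
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0, r = 10,
                      parent = -1L)
  m <- build_morphology(nodes)
  cell <- build_cell(m, passive_backbone(rm_kohm = 20), max_seg_len = 50)
  expect_equal(cell$n_comp, 1L)
  area_cm2 <- 4 * pi * (10)^2 / 1e8
  r_in <- 20e3 / area_cm2                          # Ohm
  i_nA <- 0.01
  sch <- make_schedule("somatic_injection", population = integer(0),
                       soma_amp_nA = i_nA, soma_onset_ms = 5,
                       soma_dur_ms = 100, t0_ms = 5)
  rec <- run_episode(cell, sch, duration_ms = 100, dt_ms = 0.005,
                     record_dt_ms = 0.1, record_spines = FALSE)
  sel <- rec$t >= 5 & rec$t <= 95
  t_rel <- rec$t[sel] - 5
  v_expected <- -65 + i_nA * 1e-9 * r_in * 1e3 * (1 - exp(-t_rel / 20))
  err <- max(abs(rec$soma_v[sel] - v_expected)) / (i_nA * 1e-9 * r_in * 1e3)
  expect_lt(err, 0.001)
})

test_that("passive finite cable reproduces the cosh attenuation profile", {
  # uniform cylinder; inject steady current at the soma end, compare the
  # steady-state voltage profile with cosh((L-x)/lambda)/cosh(L/lambda)
  diam <- 2; len <- 1000; rm_kohm <- 20; ra <- 100
  m <- straight_cable_morph(length_um = len, diam_um = diam, step = 10,
                            soma_r = 1)
  cell <- build_cell(m, passive_backbone(rm_kohm = rm_kohm, ra = ra),
                     max_seg_len = 5)
  lambda <- sqrt((rm_kohm * 1e3) * (diam * 1e-4) / (4 * ra)) * 1e4  # um
  sch <- make_schedule("somatic_injection", population = integer(0),
                       soma_amp_nA = 0.05, soma_onset_ms = 0,
                       soma_dur_ms = 1e5)
  apical <- which(cell$cg$comp$region == "apical_trunk")
  rec <- run_episode(cell, sch, duration_ms = 400, dt_ms = 0.05,
                     record_dt_ms = 10, record_comp = apical,
                     record_spines = FALSE)
  v_end <- rec$v[nrow(rec$v), ] + 65
  x <- cell$cg$comp$path_dist[apical]
  profile <- cosh((len - x) / lambda) / cosh(len / lambda)
  ratio <- v_end / v_end[1]
  expected <- profile / profile[1]
  expect_lt(max(abs(ratio - expected)), 0.01)
})

test_that("make_schedule respects protocol definitions", {
  pop <- 1:300
  s1 <- make_schedule("synchronous_supra", pop, n_synapses = 240, seed = 4)
  expect_length(s1$active, 240)
  expect_true(all(s1$times_ms == s1$times_ms[1]))
  expect_false(any(duplicated(s1$active)))          # activated once only
  s2 <- make_schedule("asynchronous_supra", pop, n_synapses = 240,
                      t0_ms = 20, jitter_ms = 10, seed = 4)
  expect_true(all(s2$times_ms >= 20 & s2$times_ms <= 30))
  expect_gt(length(unique(s2$times_ms)), 200)
  s3 <- make_schedule("asynchronous_supra", pop, n_synapses = 240,
                      t0_ms = 20, jitter_ms = 10, seed = 4)
  expect_identical(s2, s3)                          # same seed, same schedule
  expect_error(make_schedule("subthreshold", pop, n_synapses = 400),
               "exceeds")
  s4 <- make_schedule("somatic_plus_synapses", pop, n_synapses = 10,
                      t0_ms = 20, seed = 1)
  expect_equal(s4$iclamp$onset_ms, 33)              # 13 ms after the synapses
})

test_that("resting cell stays at rest (quiescence)", {
  cell <- desk_cell()
  sch <- make_schedule("somatic_injection", population = cell$spine$spine,
                       soma_amp_nA = 0, t0_ms = 1e9)
  rec <- run_episode(cell, sch, duration_ms = 300, record_spines = TRUE)
  half <- rec$t > 150
  # after settling, all signals flat: |dV/dt| < 0.01 mV/ms at soma and spines
  expect_lt(max(abs(diff(rec$soma_v[half]))) / 0.2, 0.01)
  drift <- apply(rec$spine_v[half, c(1, 150, 300)], 2,
                 function(v) max(abs(diff(v)))) / 0.2
  expect_true(all(drift < 0.01))
  # spine calcium at rest
  expect_lt(max(abs(rec$spine_ca[sum(half), ] - 70e-6)), 5e-6)
  expect_false(rec$ap_detected)
})

test_that("suprathreshold drive fires; subthreshold does not", {
  cell <- desk_cell()
  sup <- run_episode(cell, make_schedule("synchronous_supra",
                                         cell$spine$spine, 240, seed = 21),
                     duration_ms = 80, record_spines = FALSE)
  expect_true(sup$suprathreshold)
  sub <- run_episode(cell, make_schedule("subthreshold",
                                         cell$spine$spine, 190, seed = 21),
                     duration_ms = 80, record_spines = FALSE)
  expect_false(sub$suprathreshold)
})

test_that("run_condition bookkeeping and hypergeometric activation counts", {
  cell <- desk_cell()
  cond <- desk_supra()
  expect_equal(sum(cond$counts), 20L * 240L)
  # expected activation count per spine 20 * 190/300; Poisson-like 4 sigma
  expected <- 20 * 240 / 300
  expect_true(all(abs(cond$counts - expected) <
                    4 * sqrt(expected) + 1e-9))
  # n_episodes = 1 reduces to run_episode
  c1 <- run_condition(cell, "synchronous_supra", n_episodes = 1,
                      n_synapses = 50, seed = 77, duration_ms = 60)
  sch <- make_schedule("synchronous_supra", cell$spine$spine, 50, seed = 78)
  rec <- run_episode(cell, sch, duration_ms = 60)
  f <- episode_features(cell, rec)
  expect_equal(sort(c1$features$spine), sort(f$spine))
  expect_equal(c1$features$peak_ca[order(c1$features$spine)],
               f$peak_ca[order(f$spine)], tolerance = 1e-12)
})

test_that("halving dt changes peak spine calcium by < 1%", {
  cell <- desk_cell()
  sch <- make_schedule("synchronous_supra", cell$spine$spine, 240, seed = 5)
  r1 <- run_episode(cell, sch, duration_ms = 80, dt_ms = 0.025,
                    record_spines = FALSE)
  r2 <- run_episode(cell, sch, duration_ms = 80, dt_ms = 0.0125,
                    record_spines = FALSE)
  idx <- match(sch$active, cell$spine$spine)
  rel <- abs(r1$spine_peak_ca[idx] - r2$spine_peak_ca[idx]) /
    r2$spine_peak_ca[idx]
  expect_lt(median(rel), 0.01)
  expect_lt(max(rel), 0.03)
})

test_that("same schedule and cell give bit-identical episodes", {
  cell <- desk_cell()
  sch <- make_schedule("asynchronous_supra", cell$spine$spine, 100, seed = 9)
  r1 <- run_episode(cell, sch, duration_ms = 60)
  r2 <- run_episode(cell, sch, duration_ms = 60)
  expect_identical(r1$spine_ca, r2$spine_ca)
  expect_identical(r1$soma_v, r2$soma_v)
})
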