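test_that("extract_features: flat trace, triangle pulse, closed-form dexp", {
  t <- seq(0, 100, by = 0.1)
  flat <- extract_features(t, rep(3, length(t)), stim_time = 30)
  expect_equal(flat$peak, 0)
  expect_equal(flat$integral, 0)
  # unit triangle of base 10 ms peaking 4 ms after the stimulus
  y <- numeric(length(t))
  up <- t >= 30 & t <= 34; dn <- t > 34 & t <= 40
  y[up] <- (t[up] - 30) / 4
  y[dn] <- (40 - t[dn]) / 6
  tri <- extract_features(t, y, stim_time = 30)
  expect_equal(tri$peak, 1, tolerance = 1e-9)
  expect_equal(tri$delay, 4, tolerance = 0.1)
  expect_equal(tri$integral, 5, tolerance = 0.01)
  # difference of exponentials: peak/argmax match the closed form
  tr <- 5; td <- 60
  yde <- ifelse(t < 20, 0, exp(-(t - 20) / td) - exp(-(t - 20) / tr))
  de <- extract_features(t, yde, stim_time = 20, window_ms = 300)
  tpk <- dexp_peak_time(tr, td)
  expect_equal(de$delay, tpk, tolerance = 0.005 * tpk + 0.1)
  expect_equal(de$peak, exp(-tpk / td) - exp(-tpk / tr), tolerance = 0.005)
  expect_error(extract_features(t, yde, stim_time = 1000), "empty")
})

test_that("features are invariant to baseline and integral is additive", {
  t <- seq(0, 200, by = 0.2)
  set.seed(4)
  y <- cumsum(rnorm(length(t), 0, 0.05)) + dnorm(t, 80, 10) * 50
  f1 <- extract_features(t, y, stim_time = 50)
  f2 <- extract_features(t, y + 17.3, stim_time = 50)
  expect_equal(f1$peak, f2$peak, tolerance = 1e-9)
  expect_equal(f1$integral, f2$integral, tolerance = 1e-9)
  expect_equal(f1$delay, f2$delay)
  # additivity over a partition of the window
  fa <- extract_features(t, y, stim_time = 50, window_ms = 75)
  sel_b <- t >= 125 & t <= 200
  base <- f1$baseline
  part2 <- trapz(t[sel_b], y[sel_b] - base)
  expect_equal(fa$integral + part2, f1$integral, tolerance = 0.02)
})

test_that("compute_attenuation implements (spine - soma) / soma", {
  expect_equal(compute_attenuation(2, 1), 1)
  expect_equal(compute_attenuation(1, 1), 0)
  expect_equal(compute_attenuation(5, 0.25), 19)
  expect_true(is.na(compute_attenuation(5, 0)))     # flagged record
})

test_that("aggregate_features applies the >= 10 activation filter", {
  info <- data.frame(spine = 1:3, path_dist = c(100, 200, 300),
                     region = "oblique")
  mk <- function(spine, n) data.frame(
    spine = spine, act_time = 20, supra = TRUE,
    peak_v = rnorm(n, 10), int_v = 1, delay_v = 2,
    peak_ca = 5, int_ca = 1, delay_ca = 3)
  set.seed(1)
  feats <- rbind(mk(1, 9), mk(2, 10), mk(3, 25))
  tab <- aggregate_features(feats, info, min_activations = 10)
  expect_setequal(tab$spine, c(2, 3))               # 9 excluded, 10 included
  expect_equal(attr(tab, "n_dropped"), 1L)
  expect_equal(tab$n[tab$spine == 3], 25)
  # all-identical traces: aggregated equals single-episode features
  expect_equal(tab$peak_ca, c(5, 5))
})

test_that("fit_double_exponential: recovery, null, and linearity in A", {
  p <- trace_gen_params(amplitude = 30, tau_rise = 8, tau_decay = 90,
                        onset = 25, noise_sd = 0)
  tr <- generate_trace(p)
  fit <- fit_double_exponential(tr$t, tr$value)
  expect_true(fit$converged && fit$significant)
  expect_equal(fit$amplitude, 30, tolerance = 1e-4 * 30)
  expect_equal(fit$tau_rise, 8, tolerance = 1e-4 * 8)
  expect_equal(fit$tau_decay, 90, tolerance = 1e-4 * 90)
  expect_equal(fit$onset, 25, tolerance = 1e-3 * 25)
  # x2 scaling doubles A, leaves time constants unchanged
  fit2 <- fit_double_exponential(tr$t, 2 * tr$value)
  expect_equal(fit2$amplitude, 2 * fit$amplitude, tolerance = 1e-6)
  expect_equal(fit2$tau_decay, fit$tau_decay, tolerance = 1e-6)
})

test_that("null traces are declared significant in at most 5% of cases", {
  hits <- vapply(seq_len(200), function(s) {
    tr <- generate_trace(trace_gen_params(amplitude = 0, noise_sd = 2,
                                          duration = 250, rate_khz = 1,
                                          seed = s))
    isTRUE(fit_double_exponential(tr$t, tr$value)$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})
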