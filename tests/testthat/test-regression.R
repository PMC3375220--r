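test_that("fit_predictor selects the right form on noiseless data", {
  x <- seq(1, 50)
  # exactly linear -> linear model, R^2 = 1
  lin <- fit_predictor(x, 3 - 0.2 * x)
  expect_equal(lin$form, "linear")
  expect_equal(lin$r_squared, 1, tolerance = 1e-9)
  expect_equal(lin$sign, -1)
  # exponential generator round trip: b recovered to 1e-6
  y <- 2 * exp(-0.01 * x)
  ex <- fit_predictor(x, y)
  expect_equal(ex$form, "exponential")
  expect_equal(unname(ex$coefficients[["b"]]), -0.01, tolerance = 1e-6)
  expect_equal(unname(ex$coefficients[["A"]]), 2, tolerance = 1e-6)
  expect_equal(ex$r_squared, 1, tolerance = 1e-9)
})

test_that("no significant fit on shuffled pairs is flagged", {
  set.seed(11)
  x <- runif(120); y <- 100 + 50 * x + rnorm(120, 0, 5)
  good <- fit_predictor(x, y)
  expect_false(good$form == "none")
  # permute y to destroy the association; repeat to guard rare false hits
  forms <- vapply(1:5, function(i) {
    fit_predictor(x, sample(y))$form
  }, character(1))
  expect_gte(sum(forms == "none"), 3)
})

test_that("fit_predictor invariances and degenerate input", {
  set.seed(2)
  x <- runif(60, 0, 10); y <- 5 * exp(0.15 * x) + rnorm(60, 0, 0.5)
  f1 <- fit_predictor(x, y)
  o <- sample(60)
  f2 <- fit_predictor(x[o], y[o])
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-8)
  expect_equal(f1$form, f2$form)
  # zero-variance x -> no-fit result
  expect_equal(fit_predictor(rep(1, 10), rnorm(10))$form, "none")
  expect_equal(fit_predictor(1:2, 2:3)$form, "none")   # n < 3
})

test_that("exponential R^2 is computed in the original domain", {
  # heteroscedastic example where log-domain and original-domain R^2 differ
  set.seed(5)
  x <- seq(0.1, 6, length.out = 80)
  y <- 10 * exp(-0.5 * x) + rnorm(80, 0, 0.3)
  y[y <= 0] <- 0.01
  fr <- fit_predictor(x, y)
  ex <- fr$candidates$exponential
  nl <- nls(y ~ A * exp(b * x), start = list(A = 10, b = -0.5))
  r2_direct <- 1 - sum(residuals(nl)^2) / sum((y - mean(y))^2)
  expect_equal(ex$r_squared, r2_direct, tolerance = 1e-6)
})

test_that("compare_distributions matches a brute-force ECDF oracle", {
  a <- c(0.1, 0.4, 0.5, 0.9, 1.3, 2.2, 2.5, 3.1, 4.0, 4.4)
  b <- c(0.2, 0.6, 1.1, 1.9, 2.0, 2.1, 3.3, 3.6, 5.0, 6.1)
  ks <- compare_distributions(a, b)
  grid <- sort(unique(c(a, b)))
  gap <- max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), 0)))
  expect_equal(ks$statistic, gap, tolerance = 1e-12)
  expect_equal(compare_distributions(a, a)$statistic, 0)
})

test_that("well-separated distributions are detected at p < 0.001", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    compare_distributions(rnorm(500), rnorm(500, 3))$p_value < 0.001
  }, logical(1))
  expect_true(all(hits))
})

test_that("signed_r2_grid covers all six features with directions", {
  set.seed(9)
  n <- 120
  tab <- data.frame(
    path_dist = runif(n, 50, 400))
  tab$peak_ca <- 80 * exp(-0.004 * tab$path_dist) + rnorm(n, 0, 2)
  tab$int_ca <- 500 - 0.8 * tab$path_dist + rnorm(n, 0, 30)
  tab$delay_ca <- 5 + 0.01 * tab$path_dist + rnorm(n, 0, 0.5)
  tab$peak_v <- 60 - 0.05 * tab$path_dist + rnorm(n, 0, 8)
  tab$int_v <- 900 - 1.2 * tab$path_dist + rnorm(n, 0, 60)
  tab$delay_v <- 2 + 0.012 * tab$path_dist + rnorm(n, 0, 0.4)
  g <- signed_r2_grid(tab)
  expect_equal(nrow(g), 6L)
  expect_setequal(g$signal, c("calcium", "voltage"))
  sgn <- setNames(g$sign, paste(g$feature, g$signal))
  expect_equal(unname(sgn[c("peak calcium", "int calcium", "peak voltage",
                            "int voltage")]), rep(-1, 4))
  expect_equal(unname(sgn[c("delay calcium", "delay voltage")]), rep(1, 2))
  expect_true(all(g$r_squared >= 0 & g$r_squared <= 1))
})
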