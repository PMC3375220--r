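#' Fit distance or attenuation against a signal feature
#'
#' Least-squares fit of \code{y} (distance or attenuation) on \code{x}
#' (the feature) with two candidate forms, a straight line \eqn{y = a +
#' b x} and an exponential \eqn{y = A e^{b x}}; among the significant
#' fits, the one with the higher \eqn{R^2} is accepted. \eqn{R^2} of the
#' exponential is computed in the original domain. Significance is an
#' F-test of the regression at \code{alpha} (the exponential is tested via
#' its original-domain F statistic with 2 fitted parameters). The
#' exponential is initialized from a log-domain linear fit (using only the
#' y > 0 points) and refined by nonlinear least squares.
#'
#' @param x feature values.
#' @param y distance (um) or attenuation values.
#' @param alpha significance level of the fit acceptance test.
#' @return list of class \code{FitResult}: \code{form} ("linear",
#'   "exponential" or "none"), \code{coefficients}, \code{r_squared},
#'   \code{sign} (direction of the monotone trend, +1/-1),
#'   \code{signed_r2} (sign * R^2), \code{p_value}, \code{n}, plus
#'   \code{candidates} with both fits.
#' @export
fit_predictor <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || var(x) == 0) {
    return(structure(list(form = "none", coefficients = NULL,
                          r_squared = NA_real_, sign = NA_real_,
                          signed_r2 = NA_real_, p_value = NA_real_, n = n,
                          candidates = list()), class = "FitResult"))
  }
  sst <- sum((y - mean(y))^2)
  f_test <- function(sse, k) {
    # regression F test: (SST - SSE)/ (k-1) over SSE/(n-k)
    if (sse <= 0) return(0)
    fstat <- ((sst - sse) / (k - 1)) / (sse / (n - k))
    pf(fstat, k - 1, n - k, lower.tail = FALSE)
  }
  # linear candidate
  lf <- lm(y ~ x)
  sse_l <- sum(lf$residuals^2)
  lin <- list(form = "linear", coefficients = coef(lf),
              r_squared = 1 - sse_l / sst, p_value = f_test(sse_l, 2))
  # exponential candidate: y = A exp(b x)
  expo <- NULL
  pos <- y > 0
  if (sum(pos) >= 3 && var(x[pos]) > 0) {
    lg <- lm(log(y[pos]) ~ x[pos])
    start <- list(A = exp(coef(lg)[[1]]), b = coef(lg)[[2]])
    # warnOnly: on noiseless data nls stops with "zero residual" conditions;
    # the coefficients at that point are still the least-squares optimum
    nl <- tryCatch(
      suppressWarnings(nls(y ~ A * exp(b * x), start = start,
                           control = nls.control(maxiter = 200,
                                                 warnOnly = TRUE))),
      error = function(e) NULL)
    cand <- list()
    if (!is.null(nl)) {
      cand$nls <- coef(nl)
    }
    cand$loglin <- c(A = unname(exp(coef(lg)[[1]])),
                     b = unname(coef(lg)[[2]]))
    sses <- vapply(cand, function(cf)
      sum((y - cf[["A"]] * exp(cf[["b"]] * x))^2), numeric(1))
    best_cf <- cand[[which.min(sses)]]
    sse_e <- min(sses)
    expo <- list(form = "exponential",
                 coefficients = c(A = unname(best_cf[["A"]]),
                                  b = unname(best_cf[["b"]])),
                 r_squared = 1 - sse_e / sst, p_value = f_test(sse_e, 2))
  }
  cands <- Filter(Negate(is.null), list(linear = lin, exponential = expo))
  sig <- Filter(function(cc) is.finite(cc$p_value) && cc$p_value < alpha, cands)
  trend_sign <- sign(coef(lf)[["x"]])
  if (length(sig) == 0) {
    best <- list(form = "none", coefficients = NULL, r_squared = NA_real_,
                 p_value = NA_real_)
  } else {
    best <- sig[[which.max(vapply(sig, function(cc) cc$r_squared, 0))]]
  }
  structure(list(form = best$form, coefficients = best$coefficients,
                 r_squared = best$r_squared, sign = trend_sign,
                 signed_r2 = trend_sign * best$r_squared,
                 p_value = best$p_value, n = n, candidates = cands),
            class = "FitResult")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param sample_a,sample_b numeric samples (nonempty).
#' @return list with \code{statistic} (max ECDF gap) and \code{p_value}.
#' @export
compare_distributions <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  ks <- suppressWarnings(ks.test(sample_a, sample_b))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Signed-R^2 grid over the six signal features
#'
#' Regresses distance (or attenuation) on each of the six per-spine
#' features (peak, integral and delay-to-peak of calcium and voltage) and
#' tabulates the accepted fit's R^2 with the sign of the correlation, in
#' the layout of the study's summary table.
#'
#' @param tab a \code{FeatureRecord} table (see
#'   \code{\link{aggregate_features}}).
#' @param target name of the column to predict (default
#'   \code{"path_dist"}; use an attenuation column for attenuation grids).
#' @return data.frame with columns feature, signal, form, r_squared, sign,
#'   signed_r2, p_value, n.
#' @export
signed_r2_grid <- function(tab, target = "path_dist") {
  feats <- c(peak_ca = "peak_ca", int_ca = "int_ca", delay_ca = "delay_ca",
             peak_v = "peak_v", int_v = "int_v", delay_v = "delay_v")
  rows <- lapply(names(feats), function(f) {
    fr <- fit_predictor(tab[[feats[[f]]]], tab[[target]])
    data.frame(feature = sub("_(ca|v)$", "", f),
               signal = ifelse(grepl("_ca$", f), "calcium", "voltage"),
               form = fr$form, r_squared = fr$r_squared, sign = fr$sign,
               signed_r2 = fr$signed_r2, p_value = fr$p_value, n = fr$n)
  })
  do.call(rbind, rows)
}
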