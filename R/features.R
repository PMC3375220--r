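#' Peak, integral and delay-to-peak of a trace
#'
#' The baseline is the mean of the \code{baseline_ms} window preceding the
#' stimulus. The peak is the maximum of the baseline-subtracted signal
#' after \code{stim_time}; the integral is the trapezoidal area of the
#' baseline-subtracted signal from \code{stim_time} to \code{stim_time +
#' window_ms}; the delay-to-peak is the time from synapse stimulation to
#' the peak. Features are invariant to adding a constant offset.
#'
#' @param t sample times, ms.
#' @param y sample values.
#' @param stim_time stimulation time, ms (must be inside the trace).
#' @param window_ms analysis window length after \code{stim_time}.
#' @param baseline_ms pre-stimulus baseline window length.
#' @return list with \code{peak}, \code{integral}, \code{delay},
#'   \code{baseline}.
#' @export
extract_features <- function(t, y, stim_time, window_ms = 300,
                             baseline_ms = 20) {
  sel <- t >= stim_time & t <= stim_time + window_ms
  if (!any(sel)) stop("empty analysis window")
  bsel <- t >= stim_time - baseline_ms & t < stim_time
  baseline <- if (any(bsel)) mean(y[bsel]) else y[which(t >= stim_time)[1]]
  yw <- y[sel] - baseline
  tw <- t[sel]
  ipk <- which.max(yw)
  list(peak = yw[ipk],
       integral = trapz(tw, yw),
       delay = tw[ipk] - stim_time,
       baseline = baseline)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' EPSP attenuation
#'
#' Attenuation of a synapse is the difference between the EPSP amplitude
#' at the synapse and at the soma, divided by the somatic amplitude:
#' \eqn{(V_{syn} - V_{soma}) / V_{soma}}. Zero when the amplitudes are
#' equal; grows with electrotonic filtering.
#'
#' @param epsp_spine_mV EPSP peak at the spine, mV.
#' @param epsp_soma_mV EPSP peak at the soma, mV; records with nonpositive
#'   somatic amplitude yield NA (flagged, excluded downstream).
#' @return attenuation (dimensionless).
#' @export
compute_attenuation <- function(epsp_spine_mV, epsp_soma_mV) {
  ifelse(epsp_soma_mV > 0, (epsp_spine_mV - epsp_soma_mV) / epsp_soma_mV,
         NA_real_)
}

#' Aggregate per-episode features into a per-spine table
#'
#' Means are taken over the episodes in which each spine was activated.
#' Spines activated fewer than \code{min_activations} times (10 in the
#' study) are dropped; the drop count is recorded in the
#' \code{"n_dropped"} attribute.
#'
#' @param features per-episode feature data.frame (from
#'   \code{\link{run_condition}}).
#' @param spine_info data.frame with \code{spine}, \code{path_dist},
#'   \code{region} (e.g. the \code{spine} table of a \code{Cell}).
#' @param min_activations minimum activation count for inclusion.
#' @return per-spine data.frame of class \code{FeatureRecord}: spine,
#'   path_dist, region, n (activation count), and the mean features.
#' @export
aggregate_features <- function(features, spine_info, min_activations = 10) {
  if (nrow(features) == 0) stop("no features to aggregate")
  sp <- split(features, features$spine)
  rows <- lapply(sp, function(d) {
    data.frame(spine = d$spine[1], n = nrow(d),
               peak_v = mean(d$peak_v), int_v = mean(d$int_v),
               delay_v = mean(d$delay_v), peak_ca = mean(d$peak_ca),
               int_ca = mean(d$int_ca), delay_ca = mean(d$delay_ca))
  })
  tab <- do.call(rbind, rows)
  n_dropped <- sum(tab$n < min_activations)
  tab <- tab[tab$n >= min_activations, , drop = FALSE]
  m <- match(tab$spine, spine_info$spine)
  tab$path_dist <- spine_info$path_dist[m]
  tab$region <- spine_info$region[m]
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- n_dropped
  class(tab) <- c("FeatureRecord", class(tab))
  tab
}

#' Fit a double exponential to a fluorescence transient
#'
#' Nonlinear least squares of \eqn{A (e^{-(t-t_0)/\tau_{decay}} -
#' e^{-(t-t_0)/\tau_{rise}}) / s + c} for \eqn{t > t_0} (s normalizes the
#' shape to unit peak, so A is the transient amplitude). The fit is
#' regarded as significant when the 99% confidence interval of A excludes
#' zero. Non-convergence is reported as an insignificant fit with missing
#' parameters.
#'
#' @param t sample times, ms.
#' @param y sample values (e.g. dF/F).
#' @param onset_guess optional initial onset estimate, ms.
#' @return list of class \code{TraceFit}: \code{amplitude},
#'   \code{tau_rise}, \code{tau_decay}, \code{onset}, \code{baseline},
#'   \code{r_squared}, \code{amplitude_ci99} (length 2), and
#'   \code{significant}.
#' @export
fit_double_exponential <- function(t, y, onset_guess = NULL) {
  stopifnot(length(t) == length(y), length(t) > 10)
  base0 <- median(y[seq_len(max(3, floor(length(y) / 10)))])
  ipk <- which.max(y)
  a0 <- max(y[ipk] - base0, 1e-6)
  on0 <- onset_guess %||% {
    thr <- base0 + 0.2 * a0
    cand <- which(y[seq_len(ipk)] >= thr)
    if (length(cand) > 0) t[max(1, cand[1] - 1)] else t[max(1, ipk - 5)]
  }
  tr0 <- max((t[ipk] - on0) / 3, 2 * diff(t[1:2]))
  td0 <- {
    below <- which(t > t[ipk] & y < base0 + a0 * exp(-1))
    if (length(below) > 0) max(t[below[1]] - t[ipk], 3 * tr0) else
      max(t[length(t)] - t[ipk], 3 * tr0)
  }
  model <- function(t, A, tr, td, on, c0) {
    tt <- t - on
    s <- {
      tp <- dexp_peak_time(tr, td)
      exp(-tp / td) - exp(-tp / tr)
    }
    c0 + A * ifelse(tt <= 0, 0, (exp(-tt / td) - exp(-tt / tr)) / s)
  }
  fit <- tryCatch(
    nls(y ~ model(t, A, tr, td, on, c0),
        start = list(A = a0, tr = tr0, td = td0, on = on0, c0 = base0),
        control = list(maxiter = 200, warnOnly = FALSE),
        algorithm = "port",
        lower = c(A = -Inf, tr = 1e-3, td = 2e-3, on = min(t), c0 = -Inf)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, tau_rise = NA_real_,
                          tau_decay = NA_real_, onset = NA_real_,
                          baseline = NA_real_, r_squared = NA_real_,
                          amplitude_ci99 = c(NA_real_, NA_real_),
                          significant = FALSE, converged = FALSE),
                     class = "TraceFit"))
  }
  cf <- coef(fit)
  res <- y - predict(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se_a <- tryCatch(sqrt(vcov(fit)["A", "A"]), error = function(e) NA_real_)
  dfree <- length(y) - length(cf)
  ci <- cf[["A"]] + c(-1, 1) * qt(0.995, dfree) * se_a
  sig <- is.finite(ci[1]) && (all(ci > 0) || all(ci < 0))
  structure(list(amplitude = cf[["A"]], tau_rise = cf[["tr"]],
                 tau_decay = cf[["td"]], onset = cf[["on"]],
                 baseline = cf[["c0"]], r_squared = r2,
                 amplitude_ci99 = ci, significant = sig, converged = TRUE),
            class = "TraceFit")
}
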