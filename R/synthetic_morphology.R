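#' Parameters for the synthetic CA1-like morphology generator
#'
#' The generator emulates the gross anatomy of a CA1 pyramidal neuron:
#' a long, tapering apical trunk carrying thin oblique side branches in
#' the stratum radiatum band, a small basal tree, and a stylized axon
#' (real reconstructions in this preparation reuse a single axon across
#' cells, so a stylized one is adequate).
#'
#' @param trunk_length apical trunk path length, um.
#' @param trunk_diam_start,trunk_diam_end trunk diameter taper, um.
#' @param n_obliques number of oblique side branches.
#' @param oblique_len_mean,oblique_len_sd oblique length distribution, um.
#' @param oblique_diam oblique diameter, um (must be below the oblique
#'   classification threshold, default 1 um).
#' @param oblique_band path-distance window (um) on the trunk where obliques
#'   attach (stratum radiatum).
#' @param n_basal number of basal dendrites.
#' @param basal_len basal dendrite length, um.
#' @param basal_diam basal dendrite diameter, um.
#' @param soma_diam soma diameter, um.
#' @param axon_length,axon_diam stylized axon geometry, um.
#' @param step sample-point spacing along branches, um.
#' @param wiggle_sd lateral jitter of trunk sample points, um (gives the
#'   3D path a realistic tortuosity).
#' @param seed integer RNG seed.
#' @return a list of class \code{MorphGenParams}.
#' @export
morph_gen_params <- function(trunk_length = 750, trunk_diam_start = 3.5,
                             trunk_diam_end = 1.2, n_obliques = 14,
                             oblique_len_mean = 120, oblique_len_sd = 40,
                             oblique_diam = 0.6, oblique_band = c(60, 380),
                             n_basal = 4, basal_len = 150, basal_diam = 1.0,
                             soma_diam = 20, axon_length = 300,
                             axon_diam = 1.0, step = 20, wiggle_sd = 1.5,
                             seed = 1L) {
  p <- as.list(environment())
  stopifnot(trunk_length > 0, trunk_diam_start > 0, trunk_diam_end > 0,
            oblique_diam > 0, oblique_len_mean > 0, soma_diam > 0,
            step > 0, n_obliques >= 0, n_basal >= 0,
            oblique_band[1] < oblique_band[2])
  class(p) <- "MorphGenParams"
  p
}

#' Generate a synthetic CA1-like Morphology
#'
#' Builds an SWC-style node table (writable with \code{\link{write_swc}})
#' and assembles it into a \code{Morphology}. The apical trunk extends along
#' +y with small lateral jitter and linear diameter taper; obliques attach
#' at uniformly random trunk positions inside \code{oblique_band} and grow
#' sideways; basal dendrites grow along -y. Reproducible under
#' \code{p$seed}.
#'
#' @param p a \code{MorphGenParams} object.
#' @return a \code{Morphology}.
#' @export
generate_ca1_morphology <- function(p = morph_gen_params()) {
  stopifnot(inherits(p, "MorphGenParams"))
  withr_seed(p$seed, {
    rows <- list(); nid <- 0L
    add <- function(type, x, y, z, r, parent) {
      nid <<- nid + 1L
      rows[[nid]] <<- data.frame(id = nid, type = type, x = x, y = y, z = z,
                                 r = r, parent = parent)
      nid
    }
    # soma: 3-point cylinder along y, total length = soma_diam
    hs <- p$soma_diam / 2
    s1 <- add(1L, 0, -hs, 0, hs, -1L)
    s2 <- add(1L, 0, 0, 0, hs, s1)
    s3 <- add(1L, 0, hs, 0, hs, s2)
    # axon from bottom soma point
    n_ax <- max(2L, ceiling(p$axon_length / p$step))
    prev <- s1
    for (i in seq_len(n_ax)) {
      prev <- add(2L, 0, -hs - i * p$axon_length / n_ax, 0,
                  p$axon_diam / 2, prev)
    }
    # apical trunk from top soma point
    n_tr <- max(2L, ceiling(p$trunk_length / p$step))
    trunk_ids <- integer(n_tr)
    trunk_arc <- numeric(n_tr)
    prev <- s3
    pos <- c(0, hs, 0)
    for (i in seq_len(n_tr)) {
      frac <- i / n_tr
      d <- p$trunk_diam_start + frac * (p$trunk_diam_end - p$trunk_diam_start)
      lateral <- rnorm(2, 0, p$wiggle_sd)
      seg <- c(lateral[1], 0, lateral[2])
      seg_y <- sqrt(max((p$trunk_length / n_tr)^2 - sum(seg^2),
                        (0.5 * p$trunk_length / n_tr)^2))
      pos <- pos + c(seg[1], seg_y, seg[3])
      prev <- add(4L, pos[1], pos[2], pos[3], d / 2, prev)
      trunk_ids[i] <- prev
      trunk_arc[i] <- frac
    }
    # obliques: attach at uniform path positions within the band
    if (p$n_obliques > 0) {
      attach_d <- sort(runif(p$n_obliques, p$oblique_band[1], p$oblique_band[2]))
      for (k in seq_len(p$n_obliques)) {
        node <- trunk_ids[which.min(abs(trunk_arc * p$trunk_length - attach_d[k]))]
        len <- max(30, rnorm(1, p$oblique_len_mean, p$oblique_len_sd))
        phi <- runif(1, 0, 2 * pi)
        dir <- c(cos(phi), runif(1, 0.05, 0.35), sin(phi))
        dir <- dir / sqrt(sum(dir^2))
        n_ob <- max(2L, ceiling(len / p$step))
        prev <- node
        base <- as.numeric(rows[[node]][c("x", "y", "z")])
        for (i in seq_len(n_ob)) {
          q <- base + dir * (i * len / n_ob)
          prev <- add(4L, q[1], q[2], q[3], p$oblique_diam / 2, prev)
        }
      }
    }
    # basal dendrites from bottom soma point
    if (p$n_basal > 0) {
      for (k in seq_len(p$n_basal)) {
        phi <- 2 * pi * (k - 0.5) / p$n_basal
        dir <- c(0.6 * cos(phi), -0.8, 0.6 * sin(phi))
        dir <- dir / sqrt(sum(dir^2))
        n_b <- max(2L, ceiling(p$basal_len / p$step))
        prev <- s1
        base <- c(0, -hs, 0)
        for (i in seq_len(n_b)) {
          q <- base + dir * (i * p$basal_len / n_b)
          prev <- add(3L, q[1], q[2], q[3], p$basal_diam / 2, prev)
        }
      }
    }
    nodes <- do.call(rbind, rows)
  })
  build_morphology(nodes)
}

#' Parameters for the synthetic fluorescence-transient generator
#'
#' @param amplitude transient amplitude A (e.g. dF/F in percent).
#' @param tau_rise rise time constant, ms (must be < \code{tau_decay}).
#' @param tau_decay decay time constant, ms.
#' @param onset transient onset time, ms.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param rate_khz sampling rate in kHz (8 kHz emulates bidirectional
#'   line-scan imaging).
#' @param duration trace duration, ms.
#' @param seed integer RNG seed.
#' @return a list of class \code{TraceGenParams}.
#' @export
trace_gen_params <- function(amplitude = 50, tau_rise = 5, tau_decay = 80,
                             onset = 20, noise_sd = 2, rate_khz = 8,
                             duration = 500, seed = 1L) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise, rate_khz > 0, duration > 0,
            noise_sd >= 0)
  p <- as.list(environment())
  class(p) <- "TraceGenParams"
  p
}

# difference-of-exponentials transient, peak-normalized to 1
dexp_shape <- function(t, tau_rise, tau_decay) {
  tpk <- dexp_peak_time(tau_rise, tau_decay)
  norm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  ifelse(t <= 0, 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / norm)
}

#' Closed-form peak time of a difference of exponentials
#'
#' For \eqn{f(t) = e^{-t/\tau_d} - e^{-t/\tau_r}} with \eqn{\tau_r <
#' \tau_d}, the maximum is at \eqn{t^* = \ln(\tau_d/\tau_r)\,\tau_d \tau_r /
#' (\tau_d - \tau_r)}.
#'
#' @param tau_rise,tau_decay time constants, ms.
#' @return peak time in ms.
#' @export
dexp_peak_time <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) * tau_decay * tau_rise / (tau_decay - tau_rise)
}

#' Generate a synthetic calcium-fluorescence trace
#'
#' A peak-normalized difference-of-exponentials transient of amplitude
#' \code{amplitude} starting at \code{onset}, sampled at \code{rate_khz},
#' plus i.i.d. Gaussian noise. Reproducible under \code{p$seed}.
#'
#' @param p a \code{TraceGenParams} object.
#' @return data.frame with columns \code{t} (ms) and \code{value}.
#' @export
generate_trace <- function(p = trace_gen_params()) {
  stopifnot(inherits(p, "TraceGenParams"))
  t <- seq(0, p$duration, by = 1 / p$rate_khz)
  t <- t[t < p$duration]
  y <- p$amplitude * dexp_shape(t - p$onset, p$tau_rise, p$tau_decay)
  if (p$noise_sd > 0) {
    withr_seed(p$seed, y <- y + rnorm(length(y), 0, p$noise_sd))
  }
  data.frame(t = t, value = y)
}

#' Write a morphology plus a provenance sidecar
#'
#' Writes the SWC file and a JSON sidecar recording the generator
#' parameters and seed.
#'
#' @param morph a \code{Morphology}.
#' @param path SWC output path (sidecar gets extension \code{.json}).
#' @param params generator parameters to record (a list), or NULL.
#' @return invisibly, the SWC path.
#' @export
write_swc_with_sidecar <- function(morph, path, params = NULL) {
  write_swc(morph, path)
  side <- sub("\\.swc$", "", path)
  meta <- list(format = "swc", n_nodes = nrow(morph$nodes),
               params = if (!is.null(params)) unclass(params))
  jsonlite::write_json(meta, paste0(side, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
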