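#' Place spines at random over the stratum radiatum dendrites
#'
#' Spine locations are sampled proportionally to dendritic length within the
#' eligible region: by default the apical trunk and oblique dendrites whose
#' path distance falls inside the stratum radiatum band. Sampling is
#' uniform per unit length and reproducible under \code{seed}.
#'
#' @param morph a \code{Morphology}.
#' @param n number of spines to place.
#' @param seed integer RNG seed.
#' @param band numeric length-2 path-distance window (um) delimiting stratum
#'   radiatum on the apical tree; default \code{c(50, 400)}.
#' @param regions region labels eligible for spines.
#' @return data.frame with one row per spine: \code{spine}, \code{section},
#'   \code{arc}, \code{path_dist}, \code{region}.
#' @export
place_spines <- function(morph, n, seed = 1L, band = c(50, 400),
                         regions = c("apical_trunk", "oblique")) {
  stopifnot(n >= 1, band[1] < band[2])
  # eligible sub-intervals (section, arc range) clipped to the band
  segs <- list()
  for (s in morph$sections) {
    if (!(s$region %in% regions) || s$length <= 0) next
    d0 <- s$start_dist; d1 <- s$start_dist + s$length
    lo <- max(d0, band[1]); hi <- min(d1, band[2])
    if (hi <= lo) next
    segs[[length(segs) + 1L]] <- c(s$id, (lo - d0) / s$length,
                                   (hi - d0) / s$length, hi - lo)
  }
  if (length(segs) == 0L) stop("no eligible dendrite in the stratum radiatum band")
  tab <- do.call(rbind, segs)
  withr_seed(seed, {
    len <- tab[, 4]
    pick <- sample.int(nrow(tab), n, replace = TRUE, prob = len / sum(len))
    u <- runif(n)
    sec <- as.integer(tab[pick, 1])
    arc <- tab[pick, 2] + u * (tab[pick, 3] - tab[pick, 2])
  })
  data.frame(spine = seq_len(n), section = sec, arc = arc,
             path_dist = path_distance(morph, sec, arc),
             region = vapply(sec, function(i) morph$sections[[i]]$region, ""))
}

# evaluate expr with a local RNG seed, restoring the global state after
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
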