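#' @useDynLib spinescale, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm median nls nls.control optimize pf qnorm
#'   qt runif rnorm sd setNames vcov ks.test var predict quantile
#' @importFrom utils read.table write.csv head tail
NULL

SWC_TYPE_CODES <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L)

#' Read a neuron morphology from an SWC file
#'
#' Parses a standard 7-column SWC file (id, type, x, y, z, radius, parent;
#' whitespace separated, \code{#} comments) and builds a \code{Morphology}
#' object: a rooted tree of unbranched sections with 3D sample points and
#' per-point diameters, in micrometres. Type codes follow the SWC standard
#' (1 = soma, 2 = axon, 3 = basal dendrite, 4 = apical dendrite); apical
#' sections are further classified into \code{apical_trunk} and
#' \code{oblique} by \code{\link{classify_regions}}.
#'
#' @param path path to an SWC file.
#' @param oblique_diam_threshold mean section diameter (um) below which an
#'   apical section branching off the trunk is labelled an oblique dendrite.
#' @return an object of class \code{Morphology}.
#' @export
read_swc <- function(path, oblique_diam_threshold = 1.0) {
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("SWC file contains no data lines: ", path)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    stop(sprintf("SWC parse error at line %d: expected 7 columns, found %d",
                 keep[which(nf != 7L)[1]], nf[nf != 7L][1]))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- keep[which(rowSums(is.na(m)) > 0)[1]]
    stop(sprintf("SWC parse error at line %d: non-numeric field", bad))
  }
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], r = m[, 6],
                      parent = as.integer(m[, 7]))
  build_morphology(nodes, oblique_diam_threshold = oblique_diam_threshold,
                   lines = keep)
}

#' Build a Morphology from an SWC-style node table
#'
#' @param nodes data.frame with columns id, type, x, y, z, r (radius, um),
#'   parent (id of parent node, -1 for the root).
#' @param oblique_diam_threshold see \code{\link{read_swc}}.
#' @param lines optional original file line number per node, used in error
#'   messages.
#' @return a \code{Morphology}.
#' @export
build_morphology <- function(nodes, oblique_diam_threshold = 1.0,
                             lines = seq_len(nrow(nodes))) {
  n <- nrow(nodes)
  if (anyDuplicated(nodes$id)) {
    dup <- nodes$id[duplicated(nodes$id)][1]
    stop(sprintf("SWC parse error at line %d: duplicate node id %d",
                 lines[which(nodes$id == dup)[2]], dup))
  }
  if (any(nodes$r <= 0)) {
    bad <- which(nodes$r <= 0)[1]
    stop(sprintf("SWC parse error at line %d: nonpositive radius", lines[bad]))
  }
  idx <- match(nodes$parent, nodes$id)      # NA for roots (-1) and orphans
  is_root <- nodes$parent < 0
  orphan <- !is_root & is.na(idx)
  if (any(orphan)) {
    bad <- which(orphan)[1]
    stop(sprintf("SWC parse error at line %d: orphan node %d (parent %d not found)",
                 lines[bad], nodes$id[bad], nodes$parent[bad]))
  }
  if (sum(is_root) != 1L) {
    stop(sprintf("SWC structure error: expected exactly one root, found %d",
                 sum(is_root)))
  }
  root <- which(is_root)
  if (nodes$type[root] != SWC_TYPE_CODES[["soma"]]) {
    stop("SWC structure error: root node must be of soma type (1)")
  }
  # cycle check: follow parents from every node; depth bounded by n
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  for (pass in seq_len(n)) {
    todo <- which(is.na(depth) & !is.na(idx) & !is.na(depth[idx]))
    if (length(todo) == 0L) break
    depth[todo] <- depth[idx[todo]] + 1L
  }
  if (anyNA(depth)) {
    bad <- which(is.na(depth))[1]
    stop(sprintf("SWC parse error at line %d: cyclic or disconnected parent reference at node %d",
                 lines[bad], nodes$id[bad]))
  }
  nodes$pidx <- idx
  morph <- list(nodes = nodes)
  morph$sections <- build_sections(nodes, idx, root)
  class(morph) <- "Morphology"
  morph <- classify_regions(morph, oblique_diam_threshold)
  morph <- annotate_path_distance(morph)
  morph
}

# Split the node tree into maximal unbranched, single-type chains.
build_sections <- function(nodes, pidx, root) {
  n <- nrow(nodes)
  nchildren <- tabulate(pidx[!is.na(pidx)], nbins = n)
  starts <- which(seq_len(n) == root |
                  (!is.na(pidx) & (nchildren[pidx] > 1L |
                                   nodes$type != nodes$type[pidx])))
  is_start <- rep(FALSE, n); is_start[starts] <- TRUE
  children <- split(seq_len(n)[!is.na(pidx)], pidx[!is.na(pidx)])
  secs <- list()
  sec_of_node <- rep(NA_integer_, n)
  # traverse in BFS order over section start nodes so parents come first
  queue <- root
  while (length(queue) > 0L) {
    s <- queue[1]; queue <- queue[-1]
    chain <- s
    cur <- s
    repeat {
      ch <- children[[as.character(cur)]]
      if (is.null(ch)) break
      cont <- ch[!is_start[ch]]
      stopifnot(length(cont) <= 1L)
      if (length(cont) == 0L) break
      chain <- c(chain, cont)
      cur <- cont
    }
    sid <- length(secs) + 1L
    sec_of_node[chain] <- sid
    # anchor: parent node of the first chain node (for non-root sections)
    anchor <- pidx[chain[1]]
    pts_idx <- chain
    pts <- as.matrix(nodes[pts_idx, c("x", "y", "z")])
    diam <- 2 * nodes$r[pts_idx]
    if (!is.na(anchor)) {
      pts <- rbind(as.numeric(nodes[anchor, c("x", "y", "z")]), pts)
      diam <- c(diam[1], diam)   # do not let parent (often soma) diameter leak in
    }
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
    secs[[sid]] <- list(
      id = sid,
      parent_section = if (is.na(anchor)) NA_integer_ else sec_of_node[anchor],
      type = nodes$type[chain[1]],
      node_idx = chain,
      points = pts,
      diam = diam,
      cum_len = c(0, cumsum(seg)),
      length = sum(seg)
    )
    # enqueue child section starts
    for (nd in chain) {
      ch <- children[[as.character(nd)]]
      if (!is.null(ch)) queue <- c(queue, ch[is_start[ch]])
    }
  }
  secs
}

#' Classify sections into anatomical regions
#'
#' Regions are \code{soma}, \code{axon}, \code{basal}, \code{apical_trunk}
#' and \code{oblique}. An apical section is part of the trunk when its parent
#' is the soma or the trunk and its mean diameter is at least
#' \code{oblique_diam_threshold}; otherwise it (and all of its apical
#' descendants) is an oblique dendrite. CA1 obliques are the thin side
#' branches of the apical shaft in stratum radiatum.
#'
#' @param morph a \code{Morphology}.
#' @param oblique_diam_threshold mean diameter cut-off in um.
#' @return the \code{Morphology} with a \code{region} label per section.
#' @export
classify_regions <- function(morph, oblique_diam_threshold = 1.0) {
  base <- c("soma", "axon", "basal", "apical")
  for (i in seq_along(morph$sections)) {
    s <- morph$sections[[i]]
    lab <- base[s$type]
    if (is.na(lab)) lab <- "unknown"
    if (lab == "apical") {
      ps <- s$parent_section
      plab <- if (is.na(ps)) "soma" else morph$sections[[ps]]$region
      lab <- if (plab %in% c("soma", "apical_trunk") &&
                 mean(s$diam) >= oblique_diam_threshold)
        "apical_trunk" else "oblique"
    }
    morph$sections[[i]]$region <- lab
  }
  morph
}

annotate_path_distance <- function(morph) {
  for (i in seq_along(morph$sections)) {
    s <- morph$sections[[i]]
    start <- if (is.na(s$parent_section)) 0 else {
      p <- morph$sections[[s$parent_section]]
      p$start_dist + p$length
    }
    morph$sections[[i]]$start_dist <- start
  }
  morph
}

#' Path distance from the soma root to a location on the tree
#'
#' Distance is measured in 3D along the dendrites: the sum of Euclidean
#' lengths of the sample-point segments from the root to the location.
#'
#' @param morph a \code{Morphology}.
#' @param section_id section index.
#' @param arc arc position in [0, 1] along the section (0 at the parent end).
#' @return distance in um.
#' @export
path_distance <- function(morph, section_id, arc = 1) {
  if (any(section_id < 1 | section_id > length(morph$sections))) {
    stop("unknown section id")
  }
  stopifnot(all(arc >= 0 & arc <= 1))
  out <- mapply(function(sid, a) {
    s <- morph$sections[[sid]]
    s$start_dist + a * s$length
  }, section_id, arc)
  as.numeric(out)
}

#' Section summary table
#'
#' @param morph a \code{Morphology}.
#' @return data.frame with one row per section: id, parent, region, length
#'   (um), mean diameter (um), path distance of the distal end (um).
#' @export
section_table <- function(morph) {
  do.call(rbind, lapply(morph$sections, function(s) {
    data.frame(section = s$id,
               parent = if (is.na(s$parent_section)) NA_integer_ else s$parent_section,
               region = s$region, length = s$length,
               mean_diam = mean(s$diam),
               end_dist = s$start_dist + s$length)
  }))
}

#' Write a Morphology to a standard 7-column SWC file
#'
#' @param morph a \code{Morphology}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_swc <- function(morph, path) {
  nd <- morph$nodes
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   nd$id, nd$type, nd$x, nd$y, nd$z, nd$r, nd$parent)
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}

#' Validate the structural invariants of a Morphology
#'
#' Checks: exactly one root of soma type, positive diameters, connected
#' acyclic tree (guaranteed at construction), and that every oblique section
#' attaches to the apical trunk or to another oblique.
#'
#' @param morph a \code{Morphology}.
#' @return TRUE invisibly; stops on violation.
#' @export
validate_morphology <- function(morph) {
  roots <- sum(vapply(morph$sections, function(s) is.na(s$parent_section), TRUE))
  stopifnot(roots == 1L)
  stopifnot(morph$sections[[1]]$region == "soma")
  for (s in morph$sections) {
    stopifnot(all(s$diam > 0), s$length >= 0)
    if (s$region == "oblique") {
      plab <- morph$sections[[s$parent_section]]$region
      stopifnot(plab %in% c("apical_trunk", "oblique"))
    }
  }
  invisible(TRUE)
}

#' @export
print.Morphology <- function(x, ...) {
  tab <- section_table(x)
  cat("Morphology:", nrow(x$nodes), "nodes,", nrow(tab), "sections\n")
  agg <- stats::aggregate(length ~ region, tab, sum)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %8.1f um\n", agg$region[i], agg$length[i]))
  }
  invisible(x)
}
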