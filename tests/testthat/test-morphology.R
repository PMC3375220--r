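test_that("read_swc parses a tiny morphology and computes section lengths", {
  m <- read_swc(swc_tiny())
  expect_s3_class(m, "Morphology")
  tab <- section_table(m)
  expect_equal(nrow(tab), 2L)
  dend <- tab[tab$region == "basal", ]
  expect_equal(dend$length, 10)
})

test_that("read_swc reports structured errors naming the offending line", {
  # node whose parent id is its own id -> cycle
  expect_error(read_swc(swc_file(c("1 1 0 0 0 5 -1", "2 3 0 5 0 1 2"))),
               "cyclic|disconnected")
  # orphan node
  expect_error(read_swc(swc_file(c("1 1 0 0 0 5 -1", "2 3 0 5 0 1 9"))),
               "orphan")
  # nonpositive radius, line number in message
  expect_error(read_swc(swc_file(c("1 1 0 0 0 5 -1", "2 3 0 5 0 0 1"))),
               "line 2.*radius")
  # two roots
  expect_error(read_swc(swc_file(c("1 1 0 0 0 5 -1", "2 1 0 5 0 5 -1"))),
               "exactly one root")
  # malformed column count
  expect_error(read_swc(swc_file(c("1 1 0 0 0 5"))), "7 columns")
})

test_that("generator output survives an SWC round trip", {
  m1 <- generate_ca1_morphology(morph_gen_params(seed = 42))
  path <- tempfile(fileext = ".swc")
  write_swc(m1, path)
  m2 <- read_swc(path)
  len1 <- vapply(m1$sections, `[[`, 0, "length")
  len2 <- vapply(m2$sections, `[[`, 0, "length")
  expect_equal(len1, len2, tolerance = 1e-9)
  reg1 <- vapply(m1$sections, `[[`, "", "region")
  reg2 <- vapply(m2$sections, `[[`, "", "region")
  expect_identical(reg1, reg2)
})

test_that("path_distance: root, straight section, zig-zag oracle", {
  m <- straight_cable_morph(length_um = 100, step = 10)
  expect_equal(path_distance(m, 1, 0), 0)
  apical <- which(vapply(m$sections, `[[`, "", "region") == "apical_trunk")
  expect_equal(path_distance(m, apical, 0.5),
               m$sections[[apical]]$start_dist + 50)
  # zig-zag: brute-force point-wise summation
  set.seed(7)
  pts <- cbind(cumsum(runif(6, 1, 5)), cumsum(runif(6, -3, 3)),
               cumsum(runif(6, -2, 2)))
  nodes <- data.frame(id = 1:7, type = c(1L, rep(4L, 6)),
                      x = c(0, pts[, 1]), y = c(0, pts[, 2]),
                      z = c(0, pts[, 3]), r = c(5, rep(1, 6)),
                      parent = c(-1L, 1:6))
  mz <- build_morphology(nodes)
  brute <- sum(sqrt(rowSums((rbind(c(0, 0, 0), pts)[-1, ] -
                             rbind(c(0, 0, 0), pts)[-7, ])^2)))
  expect_equal(path_distance(mz, 2, 1), brute, tolerance = 1e-12)
})

test_that("path_distance is monotone from root to tips", {
  m <- generate_ca1_morphology(morph_gen_params(seed = 3))
  for (s in m$sections) {
    arcs <- seq(0, 1, by = 0.25)
    d <- path_distance(m, rep(s$id, length(arcs)), arcs)
    expect_true(all(diff(d) >= 0))
    if (!is.na(s$parent_section)) {
      expect_gte(path_distance(m, s$id, 0) + 1e-9,
                 path_distance(m, s$parent_section, 1) - 1e-9)
    }
  }
})

test_that("oblique classification: thin apical side branches off the trunk", {
  m <- generate_ca1_morphology(morph_gen_params(seed = 1))
  validate_morphology(m)
  regs <- vapply(m$sections, `[[`, "", "region")
  expect_true(any(regs == "oblique"))
  expect_true(any(regs == "apical_trunk"))
  for (s in m$sections) {
    if (s$region == "oblique") {
      expect_lt(mean(s$diam), 1.0)
    }
  }
})

test_that("place_spines respects region, band, seed and length-proportionality", {
  m <- generate_ca1_morphology(morph_gen_params(seed = 2))
  sp1 <- place_spines(m, 200, seed = 11)
  sp2 <- place_spines(m, 200, seed = 11)
  expect_identical(sp1, sp2)                      # determinism
  expect_true(all(sp1$region %in% c("apical_trunk", "oblique")))
  expect_true(all(sp1$path_dist >= 50 & sp1$path_dist <= 400))
  expect_error(place_spines(m, 10, band = c(5000, 6000)), "eligible")

  # two-section cable with lengths 100 vs 300 within the band:
  nodes <- data.frame(
    id = 1:5, type = c(1L, 4L, 4L, 4L, 4L),
    x = 0, y = c(0, 100, 200, 300, 400), z = 0,
    r = c(5, 2, 2, 2, 2), parent = c(-1L, 1L, 2L, 3L, 4L))
  # a branch point at node 2 creates sections [0,100] and [100,400]
  nodes <- rbind(nodes, data.frame(id = 6L, type = 4L, x = 50, y = 100,
                                   z = 0, r = 0.4, parent = 2L))
  mb <- build_morphology(nodes)
  sp <- place_spines(mb, 4000, seed = 5, band = c(0, 400),
                     regions = c("apical_trunk", "oblique"))
  first <- sum(sp$path_dist <= 100)
  # eligible length 450 (100 + 300 trunk + 50 oblique); expect p = 100/450
  p <- 100 / 450
  expect_lt(abs(first - 4000 * p), 3 * sqrt(4000 * p * (1 - p)))
})
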