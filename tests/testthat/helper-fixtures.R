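# shared fixtures; heavy objects built once per test run and memoised

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# write SWC text lines to a temp file, return path
swc_file <- function(lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}

# minimal 3-node SWC: point soma + 2-node dendrite of total length 10 um
swc_tiny <- function() {
  swc_file(c(
    "# tiny",
    "1 1 0 0 0 5 -1",
    "2 3 0 5 0 0.5 1",
    "3 3 0 10 0 0.5 2"))
}

# a single straight apical cable morphology (for cable-equation oracles):
# point soma + uniform-diameter apical cylinder
straight_cable_morph <- function(length_um = 400, diam_um = 2, step = 10,
                                 soma_r = 5) {
  n <- length_um / step
  nodes <- data.frame(
    id = seq_len(n + 1L), type = c(1L, rep(4L, n)),
    x = 0, y = c(0, seq(step, length_um, by = step)), z = 0,
    r = c(soma_r, rep(diam_um / 2, n)),
    parent = c(-1L, seq_len(n)))
  build_morphology(nodes)
}

# purely passive backbone (no channels) with configurable passive values
passive_backbone <- function(rm_kohm = 20, ra = 100, e_pas = -65) {
  structure(list(
    name = "passive-test", temperature_c = 34, v_init_mV = e_pas,
    ap_threshold_mV = 0, ca_e_mM = 2,
    passive = list(cm_uF_cm2 = 1, rm_kohm_cm2 = list(default = rm_kohm),
                   ra_ohm_cm = list(default = ra, spine = 50),
                   e_pas_mV = e_pas),
    mechanisms = list(),
    shaft_calcium = list(enabled = FALSE),
    ltype_rule = NULL), class = "BackboneConfig")
}

# desk-scale synthetic cell shared by the heavier tests
desk_cell <- function() {
  fixture("desk_cell", function() default_synthetic_cell(seed = 1))
}

desk_supra <- function() {
  fixture("desk_supra", function() {
    cell <- desk_cell()
    run_condition(cell, "synchronous_supra", n_episodes = 20,
                  n_synapses = 240, seed = 1, duration_ms = 120)
  })
}
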