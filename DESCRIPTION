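Package: spinescale
Title: Spine Calcium Signalling by Backpropagating Action Potentials and
    Homeostatic Synaptic Democracy in a CA1 Pyramidal Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multicompartment cable model of a CA1 pyramidal neuron with
    explicit dendritic spines, used to study whether voltage and calcium
    signals evoked in spines by synaptically-generated backpropagating
    action potentials carry information about synapse location and EPSP
    attenuation. Includes an SWC morphology reader and a synthetic CA1-like
    morphology generator, NMDA/AMPA receptor and R-type calcium channel
    mechanisms with Goldman-Hodgkin-Katz calcium flux and magnesium block,
    first-order spine calcium kinetics, stimulation protocols, per-spine
    feature extraction (peak, integral, delay-to-peak), linear/exponential
    distance regression, attenuation-based synaptic scaling, and a
    homeostatic plasticity rule that drives peak spine calcium towards a
    common target, establishing distance-independent somatic EPSPs
    (synaptic democracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
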