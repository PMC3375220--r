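---
title: "Methods: spine calcium signals from backpropagating action potentials and homeostatic synaptic democracy"
author: "spinescale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine calcium and synaptic democracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

CA1 pyramidal neurons receive Schaffer-collateral synapses at path
distances from tens to hundreds of micrometres from the soma. Because of
cable filtering, equal synaptic conductances produce unequal somatic
EPSPs; in real CA1 cells this inequality is compensated by
distance-dependent synaptic scaling ("synaptic democracy"). The candidate
distance cue studied here is the backpropagating action potential (BAP):
when action potentials are evoked *synaptically* — as in vivo — do the
voltage and calcium signals it produces in individual spine heads carry
enough information about synapse location to drive such scaling?

`spinescale` implements this study as a reproducible pipeline: a
multicompartment cable model of a CA1-like neuron with explicit two-
compartment spines, synaptic (AMPA, NMDA) and voltage-gated (R-type)
spine mechanisms, stimulation protocols, per-spine feature extraction,
the linear/exponential distance regressions, and the homeostatic
peak-calcium learning rule.

## The model

### Cable model and discretization

A morphology is a rooted tree of unbranched sections (soma, axon, basal,
apical trunk, obliques) with 3D sample points and diameters in µm; SWC
files are read and written directly. Sections are discretized into
frustum compartments (`max_seg_len` = 10 µm default; halving it changes
passive input resistance by < 0.5%, asserted in the suite). The voltage
equation is advanced by backward Euler with a direct Hines solve on the
tree; gates and calcium pools are advanced by exact exponential updates
between voltage solves (operator splitting), default `dt` = 0.025 ms.
Halving `dt` changes peak spine calcium by < 1% on the default protocol.

### Spines

Each spine adds two passive cylindrical compartments — neck (0.2 × 1.0
µm) and head (0.4 × 0.2 µm) — with Rm = 10 kΩcm² and Ra = 50 Ωcm. The
head carries AMPA, NMDA and R-type mechanisms. Spine-head calcium obeys
first-order kinetics,

  d[Ca]/dt = −I_Ca / (2 F v κ) − ([Ca] − [Ca]_0)/τ_Ca,

with [Ca]_0 = 70 nM, τ_Ca = 12 ms, κ = 20, head volume v, and no
diffusion through the neck. The update is the exact exponential solution
for a current held constant over the step, hence unconditionally stable.

### Synaptic and voltage-gated mechanisms

* **AMPA**: dual-exponential conductance (0.2 ms rise, 5 ms decay),
  peak 200 pS per synapse in unscaled simulations; current split 99.8%
  nonspecific : 0.2% calcium.
* **NMDA**: sum-of-exponentials open-conductance time course (rise
  1.7 ms; decays 68 and 444 ms, measured at 22 °C and Q10-corrected to
  34 °C with Q10 = 3), peak-normalized to 45 pS. The fast:slow decay
  weight (0.8:0.2) is not printed in the source recordings and only
  affects kinetics, never amplitude, because normalization re-enforces
  the 45 pS peak. Magnesium block is instantaneous and sigmoidal,
  B(V) = 1/(1 + ([Mg]/K₀)e^(−2δFV/RT)). The nonspecific current uses a
  linear driving force (E = 0 mV); the calcium current uses the GHK
  driving force (below) scaled by a calcium-permeability factor.
* **R-type**: I = ḡ m² h V_Ca(V) with ḡ = 170 pS (10 channels × 17 pS);
  Boltzmann steady states and bell-shaped time constants recorded at
  22 °C, Q10 = 3 scaled to 34 °C.
* **GHK driving force**: V_Ca(V) = V([Ca]_i e^ξ − [Ca]_e)/([Ca]_e(e^ξ −
  1)), ξ = 2FV/RT, with the analytic limit at V = 0. The normalization is
  chosen so dI/dV → ḡ at large negative V, i.e. ḡ is the channel's slope
  conductance — which makes the 170 pS figure directly interpretable.

### The backbone

The dendritic shaft/soma/axon channel set is a generic Hodgkin–Huxley
schema loaded from one versioned JSON file
(`inst/extdata/backbone_synthetic.json`): per-mechanism reversal,
per-region densities (mS/cm²) with optional linear path-distance
gradients, and one or two gates with Boltzmann steady states and
constant or bell time constants. The original channel densities were fit
to a specific reconstructed morphology and are not printed in the text;
they are therefore **config inputs**. The shipped synthetic profile was
calibrated once, and then frozen, to satisfy the study's stated
macroscopic properties:

* a somatic 50 ms current pulse elicits a single action potential
  (amplitude auto-tuned by bisection, `find_rheobase()`);
* the BAP propagates into the apical trunk with monotonically decreasing
  amplitude (Na density decreasing, A-type K increasing with distance);
* oblique dendrites regenerate brief local spikes (high local Na), so
  spine peak *voltage* is a poor distance predictor while the narrow
  oblique spikes contribute little calcium — the paper's mechanism for
  why peak calcium outperforms peak voltage;
* a small persistent Na current and a T-type window current near the
  soma sustain a proximally-biased after-depolarization (the
  voltage-integral distance signal);
* a distally increasing leak steepens distal EPSP attenuation, standing
  in for the reconstruction's leaky distal membrane;
* a single somatically-evoked BAP produces ~1 µM peak calcium in a
  mid-trunk spine (the calibration property stated for the R-type
  parameters).

The L-type-like calcium mechanism obeys the rule that its density over
the first 50 µm of the apical shaft equals the distal density; the rule
is applied when densities are instantiated per compartment and is
covered by a unit test.

### Two deliberate departures from textbook parameter values

Both are documented here because the printed equations for the Mg block
and the R-type kinetics are figure placeholders in the available text,
and because the paper's own printed *outputs* constrain the model more
tightly than the missing equations do:

1. **Mg-block steepness.** A single Woodhull barrier with δ < 1 gives an
   e-fold voltage sensitivity of ≥ 16 mV. With that slope, the NMDA
   calcium influx during the seconds-long synaptic depolarization
   envelope dwarfs the influx time-locked to the BAP, and peak spine
   calcium carries no distance information at all. The cited block model
   is a *trapping* model whose steady-state block curve is steeper than a
   single barrier; we use an effective δ = 1.3 (e-fold ≈ 10 mV),
   config-exposed.
2. **NMDA calcium-permeability factor.** The ratio of the calcium to the
   nonspecific flux "derives from the ratio of calcium to caesium
   permeability"; no number is printed. The factor (`ca_perm_ratio` = 6)
   was calibrated once against the printed subthreshold peak-calcium
   range (26–32 µM) and then frozen. A 10%-of-charge reading of the same
   sentence yields peak calcium an order of magnitude below every value
   the paper prints, so it cannot be what the original model did.

## Stimulation protocols and features

Episodes activate a random subset of the spine population once each
(synchronous; asynchronous with i.i.d. activation times in a 10 ms
window; subthreshold = fewer synapses, no somatic AP; somatic current
injection; somatic injection 13 ms after sparse synaptic drive). A
condition repeats episodes with fresh subsets; desk-scale defaults are
20 episodes with 220 of 300 spines active (full scale: 100 episodes,
240/190 of 600 — the printed counts). Per activated spine and episode we
measure peak, integral, and delay-to-peak (from that synapse's own
activation time) of head voltage and calcium; baseline is the mean over
the 20 ms before stimulation, the integral window 300 ms (both
config-exposed; the source text does not state them). Spines activated
fewer than 10 times are excluded from analysis. EPSP attenuation,
(V_syn − V_soma)/V_soma, is measured in dedicated single-synapse probe
episodes.

Why 220/174 rather than a plain 40%/32% scaling of 240/190: the somatic
AP threshold of the calibrated desk cell sits at ≈ 200 synchronously
active synapses, and 20 episodes × (220/300) also gives an expected
activation count of ≈ 14.7, keeping the ≥ 10-activation filter
meaningful. The supra:sub ratio of the paper (240:190) is preserved.

## Statistics

For each feature x we fit distance (or attenuation) y as y = a + bx and
y = Ae^{bx} by least squares (exponential initialized from the
log-domain linear fit, refined by `nls`, R² always computed in the
original domain). Among fits passing an F-test at α = 0.05 — the source
does not name its test — the one with higher R² is accepted, and its R²
is reported signed by the direction of the monotone trend. Distribution
shifts are compared with the two-sample Kolmogorov–Smirnov test.
Fluorescence transients are fit with an onset + difference-of-
exponentials model; a fit is significant when the amplitude's 99%
confidence interval excludes zero.

## Homeostatic rule

All synapses start at g_AMPA = 200 pS. Each run activates a fresh random
suprathreshold subset; every *activated* synapse is updated from its
peak calcium in that run (sub- and suprathreshold responses both
update):

  g ← max(0, g (1 + k([Ca]_T − Ca_peak)/[Ca]_T)),  k = 0.1, [Ca]_T = 47 µM.

The printed form of the update is a placeholder; this multiplicative-
relative rule has the stated fixed point, the stated directions, a
dimensionless k, and converges within a few hundred runs (500 at full
scale; 200 at desk scale). An additive variant is selectable. Democracy
is quantified as the slope and R² of somatic EPSP amplitude against
distance before and after learning; spines whose conductance collapses
to the floor are reported as a separate fraction.

## What the synthetic generator emulates — and what it does not

`generate_ca1_morphology()` produces a tapering apical trunk (750 µm
default) with thin oblique side branches attached uniformly at random in
the stratum-radiatum band (60–380 µm), a small basal tree, and a
stylized axon; `generate_trace()` produces difference-of-exponentials
ΔF/F transients with Gaussian noise at line-scan-like sampling (8 kHz).
A green desk-scale test therefore establishes that the *mechanisms* —
BAP-gated NMDA/R-type calcium, feature extraction, model selection,
homeostatic convergence — behave and order as reported, on a cell with
CA1-like gross anatomy. It does not establish quantitative agreement
with the reconstructed-morphology R² values, which depend on the full
fitted channel distributions (ModelDB accession 144490, accepted by the
schema as an alternative profile but not shipped). One directional
result resists the synthetic reduction: the strongly negative
subthreshold delay-to-peak-calcium correlation (−0.87 in the reference
analysis) does not emerge — the delay trend is at most weakly negative
and not accepted as a significant fit — because the compact synthetic
tree has a spatially near-uniform subthreshold voltage envelope that
decays with a single membrane time constant, so delay-to-peak varies by
only a couple of milliseconds across the tree. The corresponding
acceptance test is intentionally left failing rather than weakened.

## Numerical choices

* Semi-implicit scheme: conductance-like currents (leak, HH, AMPA, NMDA
  nonspecific with the unblocked fraction frozen at V(t)) are implicit in
  V; GHK calcium currents are explicit sources (they are ≤ a few pA).
* Calcium pools use the exact exponential update; concentrations are
  clipped at 0 (reachable only by roundoff).
* AP detection: upward crossing of 0 mV at the soma.
* Rest: every cell is equilibrated for 500 ms at build time and episodes
  start from the stored rest state, so probe EPSPs of ~0.1 mV are not
  contaminated by settling drift.
* Divergence (non-finite or |V| > 500 mV) aborts with the time of
  failure.

## Known limitations

* No GABAergic inhibition (as in the study), no synaptic
  depression/facilitation, no stochastic channel gating, no intra-
  dendritic calcium diffusion.
* The shaft calcium pool is a thin submembrane shell used for
  qualitative trunk profiles only.
* The backbone is a calibrated stand-in, not the fitted reconstruction;
  quantitative R² values at full scale are out of reach without the
  deposited model and hours of compute.
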