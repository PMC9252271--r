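---
title: "Feedback-circuit models of the Drosophila antennal lobe: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-circuit models of the Drosophila antennal lobe: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antennalobe)
```

# Scope

The antennal lobe (AL) of *Drosophila* transforms olfactory sensory neuron
(OSN) input into projection neuron (PN) output through a feedforward path
that is structurally simple and a local-neuron (LN) feedback web that is
anything but: LNs receive from and project back onto both OSN axon
terminals and PN dendrites, within and across glomeruli, forming a massive
number of nested feedback loops. This package provides the computational
chain needed to study that feedback logic quantitatively:

1. **Extraction** — derive, from per-synapse tables, how each LN connects
   to the four ports of each glomerulus, and which feedback-loop class it
   forms.
2. **Odorant space** — represent stimuli receptor-centrically, as binding
   and dissociation rate tensors plus concentration waveforms.
3. **Composition** — assemble executable circuits from glomeruli and
   abstract feedback motifs.
4. **Execution** — integrate the resulting conductance-based spiking
   network and characterize steady-state PN responses.

# Port patterns and feedback-loop classes

Each glomerulus exposes four LN ports: (i) LN→OSN (realized as
presynaptic modulation of the OSN axon terminal), (ii) OSN→LN,
(iii) LN→PN, (iv) PN→LN. An LN's innervation of a glomerulus is coded as
a 4-digit binary pattern in that port order; `"1100"`, for example, is an
LN that loops with the OSNs but ignores the PNs. There are 15 nonzero
patterns, of which 8 close an intra-glomerular loop (patterns matching
`11xx`, `xx11` or `1xx1`).

The extraction rules, with their thresholds collected in
`extraction_config()`, are deliberately literal:

* a synapse counts only if **both** site confidences are strictly above
  0.70;
* an LN enters the analysis only with strictly more than 10 synapses in
  the table;
* a pattern is `"0000"` when the LN's glomerular total is strictly below
  5; otherwise digit *k* is 1 exactly when the *k*-th directed count is
  strictly above 5;
* loop classes over a scope: OSN-LN-OSN requires both OSN-directed totals
  strictly above 5 and the PN totals (both directions summed) strictly
  below 5; PN-LN-PN is the mirror image; the mixed class requires all four
  directed totals strictly above 5.

Three of these rules resolve genuine ambiguities and deserve a note:

* **The ambiguous band.** A glomerular total of at least 5 where no single
  count exceeds 5 (e.g. counts 2+2+1+1) is not covered by the two stated
  digit/total rules; composing them yields `"0000"`, which we emit, and
  `port_pattern_report()` flags such rows in an `ambiguous` column rather
  than deciding silently.
* **The mixed-loop rule.** The mixed OSN/PN class is described verbally in
  the literature; the numeric form used here (all four totals above the
  loop threshold) mirrors the style of the two pure rules and is recorded
  as this package's construction.
* **PN totals.** "Fewer than 5 synapses with the PNs" is read as the sum
  of both directions; reading each direction separately would only widen
  the pure classes. The choice is recorded here and the per-direction
  totals remain available from `count_port_synapses()`.

Because a per-pattern tally can count either (LN, glomerulus) pairs or
LNs, the report keeps one row per pair, from which both tallies are one
`aggregate()` away.

vPNs (lateral-horn-only projection neurons) are excluded from PN port
counts by default (`exclude_vpn = TRUE`), since the glomerular PN
abstraction targets the uniglomerular PNs that project to both mushroom
body and lateral horn.

# Odorant space

A stimulus is identified receptor-centrically by the tensor trio
(**b**, **d**, **u**(t)): per-(receptor, odorant, neuron) binding rates
**b** (documented as 1/(concentration·s); no physical calibration is
asserted, because all downstream characterization uses the dimensionless
product), dissociation rates **d** (1/s), and per-odorant concentration
waveforms **u**(t) ≥ 0. By default rates are shared across neurons
expressing the same receptor. A *pure odorant* has u zero on every other
odorant channel. The single scalar that organizes all steady-state
analyses is the **concentration-modulated affinity**

$$A \;=\; \frac{b}{d}\,u ,$$

swept on log grids by `affinity_sweep_values()`. Waveforms are stored as
generator + parameters (constant, step, ramp, piecewise-linear) and
sampled on the integration grid at run time, so environments are
resolution-independent.

# Neuron, transduction and synapse dynamics

**Transduction (OTP).** The odorant transduction cascade begins with
exact first-order binding kinetics,

$$\frac{dx}{dt} = b\,u\,(1 - x) - d\,x ,$$

whose fixed point is $x^\* = A/(A+1)$. Downstream of binding this package
uses a deliberately compact cascade — a fast activation low-pass $v$
(τ = 10 ms) tracking $x$, one slow adaptation state $a$ (τ = 500 ms)
tracking $\gamma x$, and the saturating current map

$$I_{\mathrm{otp}} = I_{\max}\,\frac{v}{v + K\,(1 + a)} ,$$

with $I_{\max} = 120$, $K = 0.25$, $\gamma = 1$. The full published
transduction cascade has more states; the compact form preserves the two
properties every analysis here relies on — the steady-state current is
strictly increasing and saturating in $A$ — and both are enforced by
tests against the closed-form fixed point and a brute-force ODE oracle.

**Spike generation.** All OSNs, PNs and LNs use the Connor-Stevens point
neuron (sodium, delayed-rectifier potassium, transient A-type potassium),
with the canonical published parameter set recorded in
`inst/params/connor_stevens.yaml`. The A-current makes the model type-I:
firing rates grow continuously from zero above rheobase (~8.2 µA/cm²
here), which is what lets PN rate curves encode graded input. Spikes are
detected as upward crossings of 0 mV with a 2 ms lockout; both values are
arbitrary-but-fixed reproducibility choices recorded in the same file.
Currents are point-neuron currents in µA/cm² with unit membrane area; an
externally injected "20 nA"-style current maps to amplitude 20 in these
units, a convention recorded here because physical units for a point
model are not well defined.

**Synapses.** Chemical synapses are alpha synapses: each presynaptic
spike at $t_s$ adds $\bar g\,\frac{t-t_s}{\tau} e^{1-(t-t_s)/\tau}$, so a
single spike peaks at exactly $t_s+\tau$ with value $\bar g$; the current
is $g(t)(E_{\mathrm{rev}} - V)$. Excitatory: τ = 5 ms, E = 0 mV;
inhibitory: τ = 10 ms, E = −80 mV. An edge representing `count` anatomical
synapses scales linearly, $\bar g = \texttt{g\_unit} \times count$
(g_unit = 6×10⁻⁴ mS/cm²) — the simplest monotone count-to-conductance
rule.

**Presynaptic terminals.** LN→OSN port connections do not open a somatic
conductance; they divisively modulate the OSN axon terminal. The LN spike
train is alpha-filtered (τ = 100 ms) into an activity $s(t)$ and the
terminal gain

$$\mathrm{gain} = \frac{1}{1 + \kappa\, s} \in (0, 1]$$

multiplies every outgoing conductance of that OSN. The divisive form is
the simplest with the right range and limits; κ scales per synapse
(`kappa_unit` = 0.02).

# Feedback motifs and composition

Motifs abstract LN populations at the level circuit diagrams use:

* **LN1** — pattern `"1100"` in each attached glomerulus: reads the OSNs,
  presynaptically inhibits their terminals. This is the gain-control
  motif.
* **LN2** — pattern `"0011"`: loops with the PNs; its output sign is a
  parameter (default excitatory, inhibitory available) because both
  variants are of interest.
* **LN3** — no glomerular ports; connects bidirectionally to other
  motifs, inputs excitatory, output inhibitory by default. It is the only
  cross-glomerular pathway in the pair circuit.

Each motif is realized as one LN neuron (a `multiplicity` parameter
allows k identical copies). `attach_motif()` creates edges exactly where
the pattern licenses them, and `audit_port_licensing()` verifies that
invariant globally on any composed circuit. The default port synapse
counts are per-partner: 12 per OSN partner, 120 per PN partner, 400 per
LN partner on LN3 edges. Counts per partner scale inversely with partner
number — a motif talking to 2 PNs concentrates far more synapses per
partner than one talking to 40 OSNs — keeping each loop's aggregate
drive in the dynamic range of its target; the values were chosen once,
as part of the model definition, so that every feedback loop is
functional (an LN2 silenced by construction would make sign comparisons
vacuous). Whether biological LN3-like neurons target LN1/LN2 with
glomerular specificity is unresolved; LN3 wiring here is
glomerulus-agnostic.

`interconnect_pair()` composes the default five-motif two-glomerulus
circuit (one LN1 and one LN2 per glomerulus, one shared LN3);
`build_crossbar()` generalizes to the full-AL hierarchical crossbar from
an LN × glomerulus pattern matrix — e.g. one produced by the extraction
pipeline, closing the loop from measured connectivity to executable
model. `circuit_to_synapse_table()` serializes a circuit back into the
extraction schema; round-tripping a crossbar through extraction
reproduces its pattern matrix exactly, which is tested.

# Numerical choices

* Fixed-step exponential-Euler co-integration of all states; one global
  dt = 0.01 ms (stiff conductances during spikes), binding advanced by
  its exact per-step update so the bound fraction cannot leave [0, 1] at
  any step size.
* Voltage-dependent gating kinetics are tabulated per run on a 0.05 mV
  grid with linear interpolation, and exp(−x) on a table of its own —
  standard practice in spiking-network engines; dt-halving changes
  steady-state rates by well under 2 % (tested).
* Spike → synapse delivery happens at the end of the detection step, so
  a spike first affects conductances on the following step; detection
  uses strict upward crossing with the 2 ms lockout breaking ties.
* Simulations are bitwise deterministic; the `simulation_config()` seed
  is recorded for reproducibility and reserved for stochastic
  extensions.
* Degenerate inputs are warnings, not errors, when the object is usable
  (all-zero feedforward matrix, all-zero motif pattern) and errors when
  it is not (zero neurons, unknown labels, unsorted grids).

# The synthetic connectome generator

Real connectome releases cannot be redistributed with a package, so all
tests run on synthetic tables with *planted* ground truth
(`generate_connectome()`): counts behind planted `1` digits are drawn
uniformly from 8–15 (strictly above the digit threshold), behind `0`
digits from 0–3 (strictly below), each LN carries at least two `1` digits
so its AL total clears the inclusion threshold, and a configurable
fraction of decoy rows falls below the confidence filter. Under these
separated ranges recovery is exact by construction, and the acceptance
suite verifies 100 % pattern and loop-class recovery on 10 glomeruli ×
200 LNs.

What this does and does not show: the generator plants separable counts
drawn uniformly, not the count distributions of a real connectome
release; passing recovery
tests demonstrates the correctness of the thresholding logic, not
robustness to borderline biological counts, which land in the flagged
ambiguous band rather than being silently classified. Dataset-specific
census numbers (such as total LN counts per hemisphere) are properties of
an external dataset and are out of scope.

The two simulation fixtures are likewise synthetic: a single glomerulus
(40 OSNs, 2 PNs) and a DM4/DL5-style pair (20 OSNs each; the second
glomerulus has exactly one PN, matching the known DL5 structure), with
deterministic feedforward count matrices (a fixed cyclic ramp over
10–20) so fixtures are identical across machines and runs.

# What the characterizations show

Steady-state PN rates over a 20-point log-spaced affinity sweep spanning
10⁻² to 10² (4 s runs, trailing 1 s window) reproduce the qualitative
motif phenotypes: without feedback the PN saturates across nearly the
whole range; LN1's presynaptic inhibition converts the curve into a
sigmoid with an interior steepest point and a compressed ceiling;
excitatory LN2 on top of LN1 amplifies the response pointwise; with
inhibitory LN2, ablating it disinhibits the PN. On the pair circuit
(8 × 8 affinity grid) the DM4 PN rate mesh varies along the DL5 axis only
when LN3 is present — ablating LN3 severs the only cross-glomerular path
and the mesh becomes exactly constant along that axis. No published
numeric rate exists for these curves, so the package's tests assert the
ordering/shape properties, not absolute rates. Problem sizes (20-point
sweep, 8 × 8 grid, 4 s runs) are the package's default characterization
protocol.

# Limitations

* The executable path drives each receptor with one active odorant
  (pure-odorant stimuli, which all characterizations use); competitive
  binding of mixtures within one receptor is not integrated.
* Point neurons only: no morphology, no compartments, no plasticity, no
  noise; determinism is a feature here, not an omission.
* The transduction cascade is the compact monotone-saturating form, not
  the full published multi-state model.
* Motif neurons are population abstractions; per-LN heterogeneity enters
  only through the crossbar's pattern matrix, not through parameter
  variation.
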