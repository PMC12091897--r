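---
title: "Field sensitivity of the two-compartment CA3 neuron: model, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field sensitivity of the two-compartment CA3 neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfield)
```

## The model

`prfield` implements the reduced two-compartment model of a CA3 pyramidal
neuron introduced by Pinsky and Rinzel (1994): a soma carrying the fast
spike-generating currents (leak, Na with instantaneous activation
m&infin;&sup2; and inactivation h, delayed-rectifier K with gate n) and a
dendrite carrying the slow burst-generating currents (leak, Ca with gate
s&sup2;, Ca-activated K with gate c and saturation
&chi;(Ca) = min(Ca/250, 1), and afterhyperpolarization K with gate q),
joined by an electrotonic coupling conductance g~c~ scaled by the somatic
area fraction p on the soma side and 1 &minus; p on the dendrite side.
Voltages use the model's shifted convention: the leak reversal sits at
0 mV, V~Na~ = +120 mV, and action potentials overshoot to 70&ndash;90 mV.
All rate functions are the canonical 1994 forms; the four ratio-type rates
have removable singularities (&alpha;~m~ at 13.1 mV, &beta;~m~ at 40.1 mV,
&alpha;~n~ at 35.1 mV, &beta;~s~ at 51.1 mV) that the implementation fills
with their analytic limits within 10^&minus;7^ mV of the singular voltage.

Two parameters are treated as the experimental knobs throughout:

* **g~c~** (mS/cm&sup2;) &mdash; how tightly soma and dendrite are coupled.
  Weak coupling lets the compartments act independently; strong coupling
  averages their potentials.
* **V~K~** (mV) &mdash; the common reversal potential of all three potassium
  currents, physiologically set by the intra/extracellular K&#8314; ratio.
  The package default is &minus;15 mV (a depolarized, high-extracellular-K
  condition); the canonical resting value is &minus;38.56 mV.

One deliberate deviation from a widely circulated parameter table: the
dendritic calcium conductance is g~Ca~ = 10 mS/cm&sup2;, the canonical 1994
value. Printed tables sometimes carry 2.1 mS/cm&sup2; in that slot (a copy
of the standard g~c~ value). With g~Ca~ that weak the dendritic Ca spike
cannot form, the model never bursts at any coupling, and none of the regime
transitions this package is built to measure exist; with the canonical
value the full catalogue appears (checked in the acceptance suite).

## How the DC field enters

A constant induced field polarizes the membrane by a fixed offset V~e~
(mV). The package adds V~e~ to the voltage inside every **ionic driving
force** &mdash; somatic currents see V~s~ + V~e~, dendritic currents
V~d~ + V~e~ &mdash; while every gating-rate function, including the
instantaneous m&infin;, is evaluated at the unshifted state voltage. The
coupling current depends only on V~d~ &minus; V~s~ and is unaffected, as
are the injected currents.

The reason for shifting only the driving forces is structural, not
aesthetic. If the offset were applied to *all* voltage dependence (rates
and driving forces alike), the substitution
&#7825; = V + V~e~ would turn the field-modified system into the
field-free system exactly: a pure change of variables, with identical
spike counts at every field amplitude. We verified this numerically during
development &mdash; the full shift produces firing rates completely
independent of V~e~. A DC field can only matter if it moves the driving
forces *relative to* the activation curves, which is precisely what the
partial shift expresses: the channel kinetics sense the local transmembrane
state, while the effective electrochemical gradient is offset by the
field-induced polarization.

With this convention a positive (forward) field strengthens the outward
currents, lowering the firing rate until the neuron rests; a negative
(reverse) field raises the rate until the neuron locks into a depolarized
plateau without spikes &mdash; depolarization block. The contiguous band of
field amplitudes with sustained firing between those two failure modes is
the **sensitivity interval**, the package's headline output.

## Integration

The system is autonomous and is integrated with the classical fixed-step
fourth-order Runge&ndash;Kutta scheme, &Delta;t = 0.1 ms, T = 7000 ms
(70&thinsp;000 steps), always starting from one common attractor state
(`pr_initial_state()`). Everything is deterministic; repeated runs are
bit-identical. A compiled (Rcpp) right-hand side carries the load
(&asymp;60 ms per run on one CPU); a plain-R reference implementation of
the same equations is exported and the test suite keeps the two in
agreement to rounding error on randomized states.

Two numerical boundaries matter:

* **Stability at strong coupling.** The soma&ndash;dendrite exchange rate
  g~c~(1/p + 1/(1&minus;p))/C~m~ crosses the RK4 stability bound
  (&asymp;2.785/&Delta;t) near g~c~ &asymp; 20 mS/cm&sup2; at
  &Delta;t = 0.1 ms, so runs there blow up in finite time (g~c~ = 21
  diverges at &asymp;450 ms). `pr_simulate()` aborts with an error naming
  the failure time by default &mdash; silent clamping would corrupt regime
  classification &mdash; or returns the finite prefix with
  `on_divergence = "truncate"`. Parameter sweeps record such points with
  regime `"diverged"` and the firing rate measurable on the finite part
  (zero here, as divergence precedes the analysis window), which is also
  how the "firing stops beyond g~c~ = 20" phenomenon presents at this
  step size: it is a property of the stated protocol, not of the
  underlying ODE (at &Delta;t = 0.05 ms the same parameters fire at
  &asymp;4 Hz).
* **Trajectory sensitivity.** Bursting solutions accumulate phase drift:
  halving &Delta;t from 0.1 to 0.05 ms leaves the spike *count* unchanged
  at the default bursting configuration but moves late spike times by up
  to &asymp;3 ms over the 7 s window. Boundary locations on a 1 mV field
  grid are stable to this, but single-trace spike times should not be
  read as sub-millisecond-accurate.

## Spike detection and regime classification

The analysis conventions live in `pr_criteria()` and are deliberately
explicit, since regime boundaries can hinge on them:

* `spike_threshold = 20` mV &mdash; in the shifted voltage convention,
  subthreshold activity stays below &asymp;15 mV and spikes overshoot far
  above, so 20 mV separates them. Detection is an upward crossing of the
  somatic state voltage, linearly interpolated between samples.
* `transient_discard = 2000` ms &mdash; the common initial state is on the
  field-free attractor; after field onset the trajectory needs to settle.
  2 s of a 7 s run leaves a 5 s analysis window.
* `intra_burst_isi_max = 25` ms &mdash; intra-burst intervals are a few ms
  and inter-burst intervals hundreds of ms, so any cut between is stable.
* `ibi_cv_max = 0.2`, `fast_burst_ibi_max = 100` ms,
  `resting_std_max = 0.5` mV, `block_voltage_min = 25` mV,
  `block_dwell_min = 1000` ms.

Spikeless traces: a plateau above `block_voltage_min` sustained for
`block_dwell_min` is **depolarization block** when essentially flat and
**subthreshold oscillation** when it visibly ripples; away from a plateau,
a flat trace is **resting**, two-sided excursions beyond half the block
voltage are **biphasic oscillation**, anything else oscillating is
subthreshold oscillation. Spiking traces are grouped into bursts; all
singletons give **periodic spiking** (or **mixed-mode oscillation** when
at least two subthreshold cycles per spike are interleaved &mdash; one
after-depolarization bump per spike does not count); alternating
singleton/multi groups give **burst&ndash;spike alternation**; multi-spike
groups with regular inter-burst intervals give **periodic bursting**
(**fast bursting** below 100 ms); intervals alternating between two values
give **period-2 bursting**, or the **two-cycle-with-subthreshold** label
when oscillation cycles ride between the bursts.

A point is **sensitive** to the field when its regime is any of the seven
spiking labels &mdash; equivalently, sustained firing excluding
depolarization block, subthreshold/biphasic oscillation, resting and
diverged points. `pr_sensitivity()` returns the maximal contiguous
sensitive run of a 1 mV field sweep; on ties it prefers the run with the
smallest lower endpoint. Endpoints are inherently quantized to the grid,
and because the classifier conventions above are ours, boundary placements
carry an intrinsic &plusmn;1 mV convention uncertainty; the acceptance
suite asserts them exactly and treats every mismatch as a visible failure
rather than loosening the comparison.

## What the synthetic fixtures do and do not establish

`pr_fixture_trace()` builds one deterministic trace per regime label from
piecewise constants, sinusoids and triangular spike templates, each
constructed to sit squarely inside one label's definition. The fixture
suite therefore establishes that the *classifier logic* implements its
stated decision rules &mdash; it says nothing about whether the *model*
produces those regimes at any particular parameter setting. Model-level
regime assertions live separately in the acceptance suite, where a handful
are knowingly red: the burst/single alternating state and the period-2
bursting state appear in our integration at slightly different bifurcation
points than the reference placements (differences of order 0.1 mS/cm&sup2;
in g~c~ or 1&ndash;2 mV in V~K~), and the subthreshold-oscillation onset
along V~K~ sits near &minus;3.5 mV rather than &minus;5 mV. Fixtures also
do not emulate real-trace nuisance structure (after-depolarizations,
slow drifts, partial-amplitude spikelets), which is why classifier
conventions were fixed against simulated traces before the fixtures were
written.

## Known limitations

* Single neuron, DC fields only: no synapses, networks, AC or noisy
  fields, no stochastic channels.
* The sensitivity interval is measured by restarting every grid point from
  the same initial state. This makes scans order-independent and
  reproducible but hides hysteresis near bifurcations.
* At &Delta;t = 0.1 ms the integrator is unusable beyond
  g~c~ &asymp; 20 mS/cm&sup2; (see above); conclusions there are
  statements about the stated protocol.
* Absolute firing rates depend on the spike-detection conventions;
  regime labels and interval boundaries are the robust surface.
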