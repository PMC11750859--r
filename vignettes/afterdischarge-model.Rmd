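---
title: "A compartmental model of depolarization-assisted afterdischarge in mossy-fiber axons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of depolarization-assisted afterdischarge in mossy-fiber axons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Hippocampal granule-cell axons (mossy fibers) can switch from their
canonical signaling mode — spikes initiated near the soma and conducted
orthodromically — to an ectopic mode in which a distal stretch of axon
becomes a spike generator of its own. Strong repetitive activity can leave
such a stretch firing persistently after the stimulus ends
(*afterdischarge*), with spikes propagating antidromically back to the soma
and orthodromically toward the terminals. Two ingredients are thought to
conspire: a small local depolarization of the axonal membrane (as produced
by extracellular K⁺ accumulation during high-frequency firing) and the
cumulative inactivation of the axonal K⁺ channels, which progressively
broadens spikes during a train and erodes the repolarizing reserve.

`mossyburst` implements this hypothesis as a reproducible simulation
pipeline: a chain-topology compartmental model, Hodgkin–Huxley (HH) style
channel kinetics defined as data, an implicit cable-equation solver,
named stimulation presets, and trace analysis that extracts the readouts
the hypothesis predicts (spike half-durations, afterdischarge statistics,
per-spike latency ordering between recording sites, rising-phase dV/dt
inflections).

## Model structure and assumptions

The morphology is a fixed unbranched chain:
soma → axon₁ → bouton₁ → axon₂ → … → bouton₁₀ → axon₁₁, i.e. 11 axonal
cylinders (0.2 µm diameter, 100 µm long) with 10 *en passant* boutons
(4 µm diameter) threaded between them and a 10 µm soma at one end.
Discretization is 1 segment per µm, giving 1150 segments for the default
build. Passive constants are uniform: C_m = 1 µF cm⁻², R_m = 10,000 Ω cm²
(leak conductance 0.1 mS cm⁻²), R_i = 110 Ω cm. Active densities are
g_Na = 50 mS cm⁻² in axons and boutons, 10 mS cm⁻² at the soma, and
g_K = 36 mS cm⁻² everywhere, with E_Na = +50 mV and E_K = −85 mV.

Choices the geometry data do not pin down, made once and kept:

* **Bouton and soma shape.** Only diameters are specified upstream; both
  are modeled as cylinders with length equal to diameter, the standard
  convention that makes the lateral cylinder area approximate the area of
  the equivalent sphere. A bouton therefore contributes 4 segments and the
  soma 10.
* **Topology of the "distal" zone.** Boutons are in-line, so the chain
  ends soma-ward of nothing: bouton 10 is flanked by axon 10 and axon 11,
  and the distal depolarization zone is exactly that triple (204
  segments). The middle and proximal zones are the analogous triples
  around boutons 6 and 2; the uniform zone is boutons 2–10 plus axons
  2–11.
* **Resting potential.** The leak reversal is set to −80 mV everywhere.
  Because the voltage-gated channels carry some resting current, the
  actual resting potential settles ~3 mV below that with the shipped
  kinetics; this offset is accepted rather than re-balanced, and every
  protocol includes an equilibration window (below) so measurements start
  from the settled state.

Local depolarization — the stand-in for extracellular K⁺ accumulation —
is modeled purely as a shift of the leak equilibrium potential `e_leak`
inside a named zone (`apply_depolarization_zone()`). No explicit
extracellular K⁺ dynamics are simulated. A consequence worth keeping in
mind when reading steady-state numbers: the depolarized compartment never
reaches the nominal `el_target`, both because it is electrically tethered
to the non-depolarized chain and because the leak is only one of several
resting conductances.

## Channel kinetics are configuration, not code

Gates are declared as `gate_spec` objects: either forward/backward rate
functions drawn from three closed-form families (exponential, sigmoid,
linoid — the linoid evaluated by its removable-singularity limit at its
singular voltage) or tabulated x_∞(V)/τ(V) curves on a uniform grid with
linear interpolation. The integrator consumes either form, so a published
rate set can be transcribed into YAML without touching code
(`load_kinetics_profile()` documents the schema).

The shipped `"default"` profile is an engine-testing set, not a claim
about mossy-fiber channels:

* Na⁺: squid-type HH m³h, voltage-shifted by −15 mV so the resting point
  sits near −80 mV instead of the classic −65 mV.
* Non-inactivating K⁺: the matching shifted HH n⁴ delayed rectifier.
* Inactivating K⁺: the same n⁴ activation multiplied by a generic
  Kv1.4-style slow inactivation gate h, tabulated from
  x_∞(V) = 1/(1 + exp((V + 50)/6)) and
  τ(V) = 15 + 1485/(1 + exp((V + 60)/7)) ms. The shape targets the
  well-known phenotype of A-type/Kv1.4 inactivation: essentially complete
  inactivation above −30 mV, high availability at −80 mV, onset time
  constants of tens of milliseconds when depolarized, and recovery at rest
  slow enough (~1.4 s here) that inter-spike intervals of 10–50 ms cannot
  undo the inactivation accumulated during a train. These constants were
  fixed when the profile was written and are not tuned against any
  simulation outcome.

A `"paper"` profile name is reserved for rate constants transcribed from
the published mossy-fiber-bouton channel models (ModelDB deposit 128079,
files `hhmfb.mod` and `KIn.mod`). The package deliberately ships no such
transcription — guessed constants would be worse than none — so
`kinetics_profile("paper")` errors with instructions until a user supplies
a transcription file. Quantitative readouts (specific afterdischarge
frequencies, half-durations to 0.01 ms) are only meaningful against that
profile; everything the package asserts about its shipped kinetics is
structural or mechanistic.

The K⁺ *variant* selector (`make_variant()`) splits the model's total K⁺
density between the inactivating and non-inactivating channel:
pure variants carry the full 36 mS cm⁻², a mixture with fraction *f*
carries *f*·g_K and (1−*f*)·g_K, so summed density is conserved exactly
for any *f*.

## Numerical scheme

The cable equation is integrated by backward Euler with staggered gating:

1. every gate advances by the exact exponential relaxation
   x ← x_∞ + (x − x_∞)·exp(−dt/τ), with x_∞ and τ evaluated at the
   pre-step voltage;
2. the voltage system — capacitive term, ionic conductances frozen at the
   new gate values, axial coupling, injection — is solved implicitly.
   The chain topology makes the system tridiagonal, solved directly by the
   Thomas algorithm in C++ (`src/cable.cpp`).

Backward Euler was chosen over Crank–Nicolson because it is free of the
oscillatory artifacts Crank–Nicolson can produce at the coarse default
step, at the cost of first-order accuracy; the convergence test verifies
the error halves when dt halves on a passive transient, and the
timestep-robustness check verifies that an evoked spike's peak time at
dt = 0.1 ms stays within 0.2 ms of a dt = 0.001 ms reference. Axial
coupling between neighbors is 1/(ρᵢ/2 + ρⱼ/2) with ρ the full-segment
axial resistance R_i·L/A. Divergence (non-finite or |V| > 1000 mV) aborts
with the offending time and segment rather than propagating NaNs.
Voltage can optionally be held at one segment (a Dirichlet row in the
solve), which is how the analytic cable-attenuation oracle is exercised.

Defaults, with units and rationale:

| parameter | default | why |
|---|---|---|
| dt | 0.1 ms | resolves the AP upstroke at acceptable cost; presets that feed dV/dt analyses use 0.01 ms |
| t_pre | 200 ms | lets voltage and slow gates settle from the nominal −80 mV initialization before the first pulse |
| t_post | 2000 ms | long enough to distinguish persistent afterdischarge from a brief rebound |
| pulse | 0.2 nA, 2 ms, into the soma center | the standard somatic stimulus of the protocols |
| steady-state tolerance | 10⁻³ mV/ms on max dV/dt | below any visible drift at the mV scale |

## Trace analysis conventions

The upstream experiments report spikes, half-durations and afterdischarge
frequencies without specifying a detector, so the package fixes one set of
conventions and applies it uniformly:

* **Detection**: upward crossings of −20 mV separated by ≥ 2 ms. The
  threshold sits well above the most depolarized baselines used (−60 mV)
  and below all spike peaks; raising it can only remove events (a tested
  monotonicity property).
* **Baseline**: the minimum over the 5 ms before the crossing, so
  late-train spikes riding on residual depolarization are measured against
  their local foot rather than the resting potential.
* **Half-duration**: width at baseline + half amplitude with linear
  interpolation on both flanks; invariant under positive affine transforms
  of the trace. A flank that never returns to the half level before the
  next event yields `NA` rather than a fabricated width.
* **Afterdischarge**: spikes later than 50 ms after the last pulse count;
  presence requires ≥ 3 of them (one rebound spike is not a discharge);
  frequency is (N−1)/(t_last − t_first). Alternative estimator conventions
  can shift frequencies by of order one inter-spike interval — a reason
  the numeric tolerances on frequency readouts should not be over-read.
* **Latency ordering**: per-site events matched to the first site's spikes
  by nearest peak time within ±5 ms; exact ties break toward the earlier
  event and are flagged, as are groups with equal peak times.
* **IS–SD inflection**: the count of rising-phase dV/dt local maxima
  reaching 10 mV/ms between threshold crossing and peak; ≥ 2 indicates the
  two-stage (initial-segment then somatodendritic) depolarization typical
  of antidromic invasion. This requires the 0.01 ms presets.

## What the synthetic fixtures do and do not show

`make_spike_train_trace()` builds traces as baseline plus analytic
templates (gaussian, triangular, biexponential) at prescribed times, with
optional seeded Gaussian noise — the only randomness in the package. The
truth table (peak time, peak, half-width) is closed-form by construction:
the gaussian FWHM is 2.3548·σ, the triangle's half-width is half its
base width, and the biexponential's comes from root-finding on the analytic
expression, not from the sampled trace. Passing the fixture-recovery tests
therefore shows that the *analysis* stages are correct to within one
sample interval; it says nothing about the biophysics. Fixtures do not
emulate conduction delays along a cable (latency tests construct shifts
explicitly), spike-shape changes during trains, or correlated noise.

## Problem sizes used by the test and acceptance runs

Full-model simulations in the tests use the 1150-segment default build;
train protocols run 50 pulses at 50 Hz with the post-stimulus window
truncated to 100 ms where only within-train metrics are needed, and the
full 2000 ms window for afterdischarge readouts. The fine-timestep
convergence reference runs 25 ms at dt = 0.001 ms. The noisy-detection
check uses 100 seeded replicates of a 10-spike, 1 s fixture at
1 mV noise. These sizes were chosen as the smallest that exercise each
contract meaningfully.

## Known limitations

* The chain is unbranched; no dendrites, no terminal arborization, no
  SWC import.
* Extracellular K⁺ is represented only through the leak-reversal shift;
  there is no activity-dependent K⁺ accumulation or clearance.
* No Ca²⁺, HCN or Markov-state channels; kinetics are strictly HH-style.
* The shipped kinetics are generic. With them the model is *more*
  excitable after a train than the transcribed mossy-fiber set would be
  (the slow generic Kv1.4-style gate accumulates inactivation readily), so
  presence/absence contrasts across stimulation panels should be read as
  profile-dependent; the mechanistic contrast — broadening and
  train-induced self-sustained firing require the inactivating variant —
  is the portable statement, and is what the acceptance checks assert.
* Output sampling equals the integration step (no decimation), so dV/dt
  analyses are exact on the stored grid but fine-dt runs produce large
  traces (~3 × 10⁵ samples per site for a full panel at 0.01 ms).

## Reproducing the quantitative outputs

`scripts/acceptance.R --seed <s> --out <file>` recomputes, from a fresh
run of the installed package: the passive RC and cable-attenuation oracle
errors, the dt-convergence peak shift, fixture-recovery errors (zero-noise
metric error and seeded noisy detection errors), the last/first somatic
half-duration ratio for both K⁺ variants, the afterdischarge outcome of
the distal-depolarization protocol, and the steady-state potential of the
depolarized distal bouton — all with the shipped default kinetics.
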