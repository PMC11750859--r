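# mossyburst

Compartmental simulation of depolarization-assisted, ectopically generated
afterdischarge in hippocampal mossy-fiber axons.

## What it is for

Granule-cell axons (mossy fibers) normally initiate spikes near the soma
and conduct them orthodromically. Under strong repetitive activation a
distal stretch of axon can instead become a spike generator of its own,
firing persistently after the stimulus train has ended (*afterdischarge*)
and driving spikes antidromically back toward the soma. The working
hypothesis this package implements and probes: a small local
depolarization of the axon (as produced by extracellular K⁺ accumulation,
modeled as a shift of the leak reversal potential in a zone) combined with
cumulative inactivation of the axonal K⁺ channels — which broadens spikes
across a train and erodes the repolarizing reserve — is sufficient to tip
the axon into the ectopic mode.

The package is for computational neuroscientists who want a small,
fully-tested, scriptable model of this phenomenon: a fixed chain
morphology (soma, 11 axonal cylinders, 10 *en passant* boutons),
declarative Hodgkin–Huxley channel kinetics, an implicit cable solver,
named stimulation presets, and trace analysis for the readouts that
discriminate ectopic from canonical firing.

## The model in brief

Membrane potential on the discretized chain obeys the compartmental cable
equation

    C_i dV_i/dt = − Σ_c g_c,i · (Π_k x_k^{p_k}) · (V_i − E_c)
                  − g_L,i (V_i − e_L,i)
                  + Σ_{j∈nbr(i)} g_ij (V_j − V_i) + I_inj,i

with HH gating variables relaxing as dx/dt = (x_∞(V) − x)/τ_x(V). Axial
coupling is g_ij = 1/(ρ_i/2 + ρ_j/2), ρ = R_i·L/A. Geometry and densities
follow the mossy-fiber defaults (0.2 µm axon, 4 µm boutons, 1 segment/µm,
1150 segments; g_Na 50 mS cm⁻² axonal / 10 somatic, g_K 36 mS cm⁻²,
C_m 1 µF cm⁻², R_m 10 kΩ cm², R_i 110 Ω cm, E_Na +50, E_K −85, rest
−80 mV). Integration is backward Euler with staggered exact-exponential
gate updates and a Thomas tridiagonal solve (C++), stable at the default
dt = 0.1 ms.

Kinetics are configuration, not code: gates are closed-form rate families
or tabulated x_∞/τ curves. The shipped `"default"` profile (shifted
squid-type HH Na⁺/K⁺ plus a generic Kv1.4-style slow inactivation gate) is
for engine testing and mechanism studies; a `"paper"` profile slot is
reserved for rate constants transcribed from the published
mossy-fiber-bouton models (ModelDB deposit 128079, `hhmfb.mod` /
`KIn.mod`) and errors with instructions until such a transcription is
supplied. See the vignette `vignettes/afterdischarge-model.Rmd` for the
full scientific account.

## Worked example

Fifty pulses at 50 Hz into the soma, with the distal zone (10th bouton and
flanking axons) depolarized to −70 mV via its leak reversal:

```r
library(mossyburst)

model <- build_mossy_fiber()
model
#> <cell_model> 22 sections, 1150 segments
#>   axon: 11, bouton: 10, soma: 1
#>   total membrane area: 1507.96 um^2

p <- protocol(frequency = 50, count = 50, zone = "distal", el_target = -70,
              record = c("soma", "bouton_10"))
traces <- run_protocol(p)   # equilibration, train, 2 s post window
traces
#> <trace_set> 31821 samples at dt = 0.1 ms; sites: soma, bouton_10

spikes <- detect_spikes(traces, site = "bouton_10")
afterdischarge_summary(spikes, stimulus_end(p), window = p$t_post)
#> afterdischarge: present | 84 post-stimulus spikes | 43.09 Hz

train <- detect_spikes(traces, site = "soma")
train <- train[train$t_peak <= traces$stim_end, ]
round(c(first = train$half_duration[1],
        last  = train$half_duration[nrow(train)]), 2)
#> first  last
#>  1.34  1.86
```

The somatic spike half-duration grows from 1.34 to 1.86 ms across the
train — use-dependent broadening from cumulative K⁺-channel inactivation —
and the train leaves the distal axon firing persistently at ~43 Hz for the
whole 2 s observation window. The ordering of spikes between sites reverses
after the train (matching window widened to cover this profile's ~10 ms
conduction delay):

```r
lo <- latency_order(traces, window = 15)
table(subset(lo$groups, t_soma <= traces$stim_end)$order)
#> soma < bouton_10
#>               50
table(subset(lo$groups, t_soma > traces$stim_end + 50)$order)
#> bouton_10 < soma
#>               84
```

Orthodromic during the train, antidromic during the afterdischarge: the
discharge originates ectopically in the depolarized distal axon. With the
non-inactivating K⁺ variant (`variant = "non_inactivating"`) the
broadening disappears (ratio ~1.03 instead of ~1.39); compare via
`run_protocol` or the presets (`list_presets()`, `run_panel("fig3c", out)`).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/mossyburst.R list-presets
Rscript inst/cli/mossyburst.R run fig1b --out out/
Rscript inst/cli/mossyburst.R analyze out/fig1b_traces.csv
```

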