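# neuroprune

Dendritic pruning and excitable dynamics on neuronal morphologies.

Aging and neurodegeneration progressively retract dendritic arbors. This
package is for computational neuroscientists who want to ask, at the level
of a single reconstructed neuron, what that retraction does to function. It
models aging as **iterative terminal pruning** — each iteration removes
every dendritic compartment without children — and runs a **stochastic
excitable cellular automaton** on each pruned stage to measure the
functional consequences.

## The model

A neuron is a rooted tree of compartments (parsed from SWC, the soma
collapsed to a single root compartment, axons stripped). Each compartment
cycles susceptible → active → refractory (7 steps) → susceptible, with
synchronous updates at resolution δt = 1 ms. A susceptible compartment with
k active neighbours becomes active with probability

    p = 1 − (1 − r)(1 − P)^k,    r = 1 − exp(−h·δt)

where *h* is the stochastic synaptic input rate (Hz) and *P* the
propagation probability along the tree. From per-compartment spike counts
S_i (soma = compartment 0, N dendritic compartments) the package derives:

- **Response function** F(h): soma firing rate versus input rate;
- **Dynamic range** Δ = 10·log₁₀(h₉₀/h₁₀), the width in input decades
  mapped between 10% and 90% of the maximal rate;
- **Energy consumption** E = ΣS_i/S₀ and **relative energy consumption**
  E_rel = E/N (E_rel < 1 ⇔ energy-efficient);
- **Soma centrality**: min–max-normalised distance (in compartments) to
  the farthest terminal compartment (1 = most central);
- a **branch–centrality classification** (Type 1/2/3/T) of functional
  stages.

Synthetic generators (chains, stars, Cayley trees, random trees, and a
pyramidal-like stand-in morphology) plus closed-form and exhaustive
Markov-chain oracles make the entire pipeline testable without any
external data.

## Worked example

```r
library(neuroprune)

neuron <- make_synthetic_pyramidal(seed = 1)   # or read_swc("cell.swc") |> collapse_soma() |> strip_axon()
summary(neuron)
#> Morphometric summary
#>   dendritic compartments: 510 (with soma: 511)
#>   bifurcations:           76
#>   somatic branches:       10
#>   soma centrality:        0.647

prune_trajectory(neuron)
#> <prune_trajectory: 47 iterations>
#>   intact: 510 dendritic compartments, 76 bifurcations, 10 stems
#>   landmarks: single stem at 22, last bifurcation gone at 22, fully pruned at 47

aged  <- snapshot_at(neuron, 24)               # morphology after 24 pruning passes
counts <- simulate_dynamics(aged,
            dynamics_params(P = 0.9, h = 10, n_steps = 20000, seed = 42))
counts
#> <spike_counts: 24 compartments, 20000 counted steps>
#>   soma (id 1): 790 spikes (39.50 Hz); dendritic total: 21061
energy(counts)
#> <energy_result: E = 26.659, E_rel = 1.1591 over N = 23 dendritic compartments>

rc <- response_curve(neuron, P = 0.9, h_grid = 10^seq(-2, 3, length.out = 11),
                     n_steps = 20000, master_seed = 42)
dynamic_range(rc)
#> <dynamic_range: delta = 31.687 (F_max = 109.35 Hz, h10 = 0.05495, h90 = 81.02)>
```

Reading: the intact neuron has ten dendritic stems and moderate soma
centrality; pruning collapses it to a single stem at iteration 22 and
erases it at 47. At 24 passes the survivor spikes at ~40 Hz but needs
~1.16 dendritic spikes per compartment for every somatic spike
(E_rel > 1: it has crossed into the energy-inefficient regime), while the
intact neuron spans ~31.7 input decades ×10 of dynamic range at P = 0.9.

`run_pipeline(run_config(...))` chains all of the above over pruning
iterations and a (P, h) grid and writes tidy CSVs; `inst/cli/neuroprune`
exposes the same steps as `synth | prune | simulate | sweep | report`
subcommands.

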