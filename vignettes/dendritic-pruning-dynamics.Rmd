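---
title: "Modelling dendritic pruning and its dynamical consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dendritic pruning and its dynamical consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroprune)
```

## The model

Aging neurons lose dendritic material: branches retract, branching order
falls, and the arbor shrinks towards the soma. `neuroprune` models this
process and asks what it does to the neuron's dynamics — its firing rate,
its energetic cost per somatic spike, and the range of input intensities it
can discriminate.

A neuron is a rooted tree of *compartments* (one SWC sample point = one
compartment; the soma is collapsed to a single compartment at the root;
axonal points are discarded). Two processes run on this tree:

**Pruning.** One aging iteration removes, simultaneously, every dendritic
compartment that has no children. Iteration 0 is the intact reconstruction.
Three landmark iterations summarise a trajectory: the first iteration with a
single somatic stem, the first with no dendritic bifurcation left (while
dendrite remains), and the iteration at which the dendrite is gone
entirely. If the stem count ever skips from two or more straight to zero,
the single-stem landmark is undefined and reported as `NA` rather than
invented.

**Excitable dynamics.** Each compartment is a probabilistic cyclic cellular
automaton with synchronous update, cycling susceptible → active →
refractory → susceptible. In one time step of length $\delta t$, a
susceptible compartment with $k$ active neighbours becomes active with
probability

$$p = 1 - (1 - r)\,(1 - P)^k, \qquad r = 1 - e^{-h\,\delta t},$$

i.e. external synaptic drive (rate $h$, in Hz) and each active neighbour
(propagation probability $P$) act as independent activation attempts. The
paper-family model specifies only the single-cause probabilities; the
independent-attempts combination is the standard choice for this model
class and is documented here as ours. Active compartments spend exactly one
step active, then `refractory_steps` steps refractory.

### Timing convention and its closed form

A compartment that leaves refractoriness becomes susceptible *at* step $t$
and can next be activated at the update that produces step $t+1$. The
minimum inter-spike interval is therefore `refractory_steps + 2` steps and
the maximal rate is $1/((\texttt{refractory\_steps}+2)\,\delta t)$ —
111.1 Hz at the defaults ($\delta t = 0.001$ s, 7 refractory steps). For an
isolated driven compartment the mean inter-spike interval is
$\texttt{refractory\_steps} + 1 + 1/r$ steps, giving the closed-form
response `isolated_rate_oracle()`, which the test-suite uses as an
independent oracle against the simulator (the other oracle being the
exhaustively enumerated synchronous Markov chain on 2–3 compartments).
Whether the original implementation allowed re-activation one step earlier
is not documented anywhere we could check; we fixed this convention once
and wrote every oracle and test against it.

### External drive policy

Stochastic synapses drive every compartment, including the soma, by
default (`drive_soma = TRUE`). The alternative reading (dendrites only) is
available as a flag. We default to driving the soma because a fully pruned
neuron — a bare soma — still responds to input in the trajectories the
model is meant to span; with `drive_soma = FALSE` its response function
would be identically zero and every derived measure undefined.

## Derived measures

* **Response function**: mean soma firing rate $F$ against drive $h$ at
  fixed $P$, one independent simulation per grid point.
* **Dynamic range**: $\Delta = 10\,\log_{10}(h_{90}/h_{10})$, where
  $h_{10}$ and $h_{90}$ produce 10% and 90% of the maximal rate $F_{max}$.
  $F_{max}$ is the maximum of the *sampled* curve (well defined for every
  curve, and at saturating drive it approaches the theoretical ceiling).
  The crossings are located by linear interpolation of $F$ in
  $\log_{10} h$ at the first upward crossing; the rule matters because $h$
  spans five decades. Thresholds not bracketed by the grid are reported as
  out-of-grid, with $\Delta$ set to `NA`, never extrapolated.
* **Energy**: $E = \sum_{i=1}^{N} S_i / S_0$ (dendritic spikes per somatic
  spike) and $E_{rel} = E/N$; $E_{rel} < 1$ is the energy-efficient regime.
  If the soma never fires, both are flagged undefined (`NA`), not infinite.
* **Parameter-space means**: unweighted arithmetic means over a grid with
  $0.5 \le P \le 1$ and $10^{-2} \le h \le 10^{3}$ Hz ($h$ log-spaced;
  default 11 × 51, configurable). Undefined cells are excluded and counted.
  $P < 0.5$ is not swept: propagation failures kill signals too quickly for
  sustained dendritic activity there.
* **Soma centrality**: a compartment's eccentricity is the number of edges
  to its farthest *terminal* compartment; centrality min–max-normalises
  eccentricity over all compartments so the most central score 1 and the
  least central 0. Degenerate trees in which every compartment is equally
  eccentric (a lone soma) score 1 by convention. Eccentricities are
  computed by an $O(n)$ two-pass dynamic program on the tree; the test
  suite checks it against an all-pairs shortest-path oracle.
* **Functional classification**: Type 2 for one somatic stem, Type T for
  bitufted (two stems), otherwise Type 1 (efficient) above a centrality
  threshold and Type 3 (inefficient) below it. The threshold defaults to
  0.3 — the centrality below which mean relative energy consumption is
  observed to cross 1 — and is an explicit parameter because the original
  boundary is not printed in the sources available to us.

## Table-1-style counting

`morphometrics()` reports the dendritic compartment count (soma excluded)
as `n_compartments` and the soma-inclusive count as
`n_compartments_total`. The energy equations index dendritic compartments
$1..N$ with the soma as compartment 0, so the dendritic count is the
documented primary; published per-reconstruction tables may follow either
convention, which is why both are always exposed and the reconstruction
checks in the test suite accept a match under one convention applied
globally.

## Synthetic morphologies and what they do (not) show

The generators produce chains, stars, Cayley trees and random recursive
attachment trees — the idealized topologies of the excitable-tree
literature — plus `make_synthetic_pyramidal()`, a stand-in with the gross
topology of a human pyramidal cell: by default 9 short branched basal
stems (heights 8–22 compartments, ~45 compartments each), one apical stem
with a 19-compartment trunk, oblique side branches, and a two-branch
terminal tuft (22–30 compartments), ~500–600 dendritic compartments in
total. These sizes were chosen once, as plausible for a NeuroMorpho-scale
pyramidal reconstruction at one-point-per-compartment resolution, and give
the stand-in the features that drive the pruning story: many stems, a
dominant apical shaft that outlives the basal arbor, a bifurcation that
persists past the single-stem stage, and intermediate intact centrality.

Geometry everywhere is decorative: unit segment lengths and radii are
carried through SWC I/O but never influence the dynamics, which are purely
topological.

What passing tests on synthetic trees show: the simulator, the pruning
algorithm and every derived measure behave exactly as specified on known
topologies, and the qualitative aging phenomenology (falling energy
consumption, an efficiency crisis near the single-stem stage at low
centrality, shrinking dynamic range partially rescued by higher $P$)
emerges on a pyramidal-like tree. What they cannot show: agreement with
any *particular* published reconstruction. The package does not bundle
NeuroMorpho reconstructions; the reconstruction-specific checks in
`tests/testthat/test-acceptance.R` (Table-1-style counts, the landmark
iterations 24/27/46 of the human pyramidal accession NMO_84457) run
against SWC files the user places under `inst/extdata/neuromorpho/`, and
fail with instructions when those files are absent.

## Reproducibility and problem sizes

Every simulation takes an explicit seed; sweeps derive one seed per
(iteration, P, h) cell from the master seed via a fixed integer hash
(`cell_seed()`), so single cells can be reproduced from their provenance
row and results are independent of execution order. The simulation core is
a small C++ routine drawing from R's RNG stream.

Reference-scale runs in the original setting use 500,000 steps per cell
over a 5-decade, fine-grained grid. The package defaults and the bundled
analysis script run a desk-scale profile — 20,000 steps per cell on a
6 × 11 grid over pruning iterations 0–40 in steps of 8 — which we chose as
the point where the trend-level statements (monotone energy decline,
efficiency crossover, dynamic-range ordering in $P$) are stable across
seeds while a full trajectory completes in about a minute. Quantitative
curve values at this scale carry visible Monte-Carlo error; only
trend-level and oracle-level statements are asserted.

## Known limitations

* No cable properties, conductances, synapse placement, or radius-dependent
  dynamics — excluded by design, the model is topological.
* Pruning is deterministic and uniform (all termini per iteration);
  stochastic terminus removal and whole-branch loss are natural extension
  hooks (`prune_once()` is the place) but are not implemented.
* Single neurons only; no networks, plasticity, or inhibition.
* The Type 1/Type 3 centrality boundary is a parameter, not a derived
  quantity.
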