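---
title: "Coevolving immune signaling networks under pleiotropic constraint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolving immune signaling networks under pleiotropic constraint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiosim)
```

`pleiosim` is an agent-based simulator of host immune signaling networks
coevolving with parasites that manipulate host signaling, built to study
when immune defense evolves to be *constitutive* (effector active before
any infection) versus *inducible* (effector activated only after
detection), and how *pleiotropy* — one signaling protein also serving
another trait, and therefore evolutionarily constrained — shifts that
balance.

## The within-host model

A host is a signed, directed protein-interaction network with one
**detector** (parasite sensing), evolving **signaling** proteins
(initially three), and one **effector** (parasite killing). Each protein
`i` exists as complementary active/inactive fractions,
`[P*_i] + [P_i] = 1`, and only the active fraction acts on others. A
single signed weight per ordered node pair encodes regulation: positive
weights are upregulatory coefficients `k[i,j]`, the magnitudes of
negative weights are downregulatory coefficients `I[i,j]`; self-edges are
permitted everywhere (evolved networks make heavy use of
self-regulation), and the one structural taboo is a direct
detector-to-effector edge. The discrete-time update for every node is

```
P*_i(t+1) = clamp01( P*_i + [P_i] * sum_j k[i,j] P*_j
                          - [P*_i] * sum_j I[i,j] P*_j
                          - use_coef * outdegree(i) )
```

applied synchronously. The last term is a flat per-step "protein use"
cost for each outgoing regulatory edge (self-edges count, and during
infection so does the effector's killing edge onto the parasite). Two
numerical choices deserve note:

* **The use cost is abundance-independent.** We read the cost as a flat
  per-edge drain, not scaled by the node's current activity; clamping to
  `[0, 1]` after each update keeps fractions physical, and the clamp is
  exactly what prevents the flat drain from producing negative
  abundances.
* **`use_coef` defaults to 0.01.** The value is configurable; the
  default is chosen so that a node wiring to every protein of a 5-node
  network (cost 0.05 per step) is penalized but not extinguished, which
  keeps early random networks viable while still selecting against
  gratuitous wiring.

The **healthy phase** starts every protein at `P* = 0.5` and iterates
until the effector moves by less than `equilibrium_tol` (default `1e-3`)
between consecutive steps, capped at 200 iterations (the cap guarantees
termination; non-convergence is flagged, not fatal). Only the effector is
tested for convergence, since the effector level is the quantity the
fitness function consumes. The equilibrium effector level
`effector_pre` is the host's constitutive investment.

## Infection and fitness

A parasite targets one signaling protein with a signed manipulation
weight in `[-1, 1]`. At infection it joins the dynamics as an extra node
with recognition (`+1` onto the detector), replication (`+0.8`
self-edge), its manipulation edge, and a `-1` killing edge from the
effector onto it; the parasite enters at abundance 0.5. The episode is
checked after every step, in order: 20 steps elapsed (the reproductive
lifespan) ends it as *managed*; parasite abundance below `1e-2` as
*cleared*; running normalized area above `0.9` as *host death* (the host
is barred from reproduction). The normalized area is always the summed
parasite trace divided by 20, whether or not the episode ended early —
this choice (over dividing by elapsed steps) makes fast clearance cheap
for the host and unrewarding for the parasite, matching the reading of
area as lifetime parasite output. Ties between clearance and death at
the same step resolve in the host's favor by the check order.

Host fitness multiplies four exponential penalties:

```
W = exp(-( effector_pre + V * area + effector_post + protein_cost ))
```

with virulence `V = 1` by default and
`protein_cost = 1.1 * (size - 10)` above a 10-protein threshold, zero
below. Constitutive investment, parasite damage, residual post-infection
investment (an unregulated inducible response pays here), and genome
size each cost fitness. Parasite fitness is simply the normalized area.
Uninfected hosts pay `effector_pre` twice (pre and post coincide), so
with no parasites around the optimum is zero immunity.

## Evolution

Each generation: healthy equilibria, infection of
`round(infection_chance * n)` hosts paired one-to-one at random with the
parasite pool, fitness, death, reproduction.

**Death** removes at most 30% of each population per generation. Hosts
killed by infection die first; if they alone exceed the cap, the excess
are resurrected at random (a deliberate concession that keeps early,
low-fitness populations alive). The remainder of the quota is filled by
visiting survivors in random order, each dying with probability one
minus its fitness percentile. We define the percentile as the fraction
of the pool with *strictly* lower fitness (ties share a value), so that
a host at the 75th percentile dies with probability exactly 0.25. The
same machinery culls parasites, using cumulative load as fitness and
prioritizing parasites of cleared or dead hosts (their within-host
lineage ended), mirroring the host rule for symmetry.

**Reproduction** draws survivors uniformly and accepts each draw with
probability equal to its fitness percentile, appending one offspring per
acceptance until the population is back to size — the mirror image of
the death rule, so that fitter hosts both die less and breed more.
Because a strict percentile makes a lone or all-tied
survivor pool sit at percentile zero, that degenerate case accepts every
draw — otherwise replenishment could never finish. Offspring are exact
copies except with probability `5e-3` (hosts) / `1e-2` (parasites) of
carrying exactly one mutation:

* hosts — add edge (.25), delete edge (.25), redraw a weight (.3),
  delete a signaling protein (.1), duplicate a signaling protein (.1);
* parasites — retarget uniformly among the host's signaling proteins
  (.5), redraw the manipulation weight (.5).

Duplication copies the full edge neighborhood, with a self-edge becoming
a self-edge on the copy rather than a cross-edge (the most conservative
reading of "duplicate"). Deletion never touches the detector, the
effector, the pleiotropic protein, a protein carrying a locked edge
(locked edges are immortal, so their endpoints must be too), or the last
signaling protein — parasites must always have a legal target. When a
drawn mutation type has no legal move, the type is redrawn.

## The four pleiotropy constraints

One of the three initial signaling proteins, chosen uniformly at
host creation, is pleiotropic:

| mode | constraint |
|---|---|
| `fixed-random` | every edge incident to it at initialization is locked forever |
| `fixed-up` | adds a locked `+1` edge onto the effector |
| `fixed-down` | adds a locked `-1` edge onto the effector |
| `slow` | nothing locked; its edge mutations run 100x slower |

Locked edges can never be deleted or re-weighted; the pleiotropic
protein can never be deleted. A *duplicated* pleiotropic protein's copy,
however, is an ordinary unconstrained signaling protein — the original
keeps its locks. The fixed up/down locked weight magnitude defaults to
1: only the *direction* of the developmental side effect is inherent to
the constraint, and the extreme of the allowed range maximizes its
phenotypic signal (a weaker side effect can be configured). Under `slow`, a drawn
edge mutation touching the pleiotropic protein is carried out with
probability 1/100 and otherwise silently dropped, which realizes the
reduced per-offspring rate without distorting the mutation-type mix of
the rest of the network.

## Simulations

`run_coevolution()` evolves one population (500 hosts for 500
generations under the reference conditions; both configurable) against
its parasites; `run_competition()` evolves a pleiotropic and a
non-pleiotropic half-population in isolation (0 or 250 generations),
merges hosts and parasites into one arena where both types compete for
the same reproductive slots under a single fitness ranking, and ends at
extinction of one type or a draw after 1000 merged generations. The
parasite pools are merged along with the hosts (rather than kept
segregated per host type), and a single merged fitness ranking is used —
without shared reproductive slots, extinction of a type could never
happen at all.

All randomness flows from one master seed through R's default RNG
stream with a fixed draw order (initialization, then per generation:
infection assignment, episode bookkeeping, culling, reproduction). Runs
are therefore bit-reproducible; `summary.tsv` written twice from the
same seed is byte-identical. We chose a single documented stream over
named substreams because base R offers no ergonomic stream splitting for
sequential code, and the determinism guarantee — the property that
matters — is identical.

The archive of a run (per-generation summary, ancestry log of every
reproduction event, final evaluated population with its infection
records, serialized networks at full float precision) is sufficient to
run every analysis below without re-simulation. The "final" population
is the last *evaluated* one — the hosts whose infections were actually
simulated — not the newborn offspring that close the run, so analysis
tables always refer to hosts with records.

## Analysis metrics

* **Inducibility** of a host: `(peak - pre) / peak` effector abundance
  over its infection, clamped to `[0, 1]`; a host that never mounts any
  response (`peak = 0`) scores 0, avoiding 0/0.
* **Response densities**: Gaussian KDE of inducibility values over a
  201-point grid on `[0, 1]`, Silverman bandwidth, reflected at both
  boundaries so no mass leaks outside the unit interval, then
  peak-normalized to 1. The kernel, bandwidth rule, and boundary
  correction are this package's choices; all three are configurable
  arguments.
* **Density correlation**: Pearson r across the shared grid;
  `|r| <= 0.2` flags substantively different immune dynamics.
* **Magnitude vs inducibility**: a 2D product-kernel analogue, estimated
  per run and summed across runs, so the raw surface integrates to the
  number of runs pooled.
* **Knockout divergence**: mean absolute effector difference over a
  fixed 20-step infection (no early termination, so both trajectories
  have equal length) between the intact network and the network with one
  signaling protein removed, each from its own healthy equilibrium,
  infected by a non-manipulating parasite. Contrasts use equal-variance
  two-tailed t-tests with Bonferroni correction.
* **Connectivity**: edges over `n^2 - 1` legal ordered pairs (self-edges
  legal, detector-to-effector not).
* **Distinct paths**: the maximum number of detector-to-effector paths
  sharing no signaling protein, computed as unit vertex-capacity max
  flow on the node-split graph; the test suite checks it against
  exhaustive enumeration on all graphs up to 8 nodes.
* **Most common network**: exact-form equality (stable node labels,
  roles, full-precision sorted edge list), ties broken by lowest host
  id. Exact matching is deliberate: clonal reproduction makes exact
  copies common, and any fuzzier equivalence would need an arbitrary
  tolerance.
* **Lineage split**: whether any generation-0 lineage ends with both a
  host at or above and one below an inducibility threshold (default
  0.5).

## What the generator emulates, and what it does not

The initializer *is* the study's data generator: random 5-protein
networks with each legal edge present with probability 1/2 and uniform
weights, the stated mutation menu and rates, infection chances in
{0.1, 0.5, 0.9}, and the fitness constants above. Defaults are the
reference conditions; nothing is tuned per run. What passing tests on
this generator show is that the *model's* dynamics, selection rules and
statistics are implemented faithfully — not that any specific biological
pathway behaves this way. The networks are small and abstract, effectors
kill with perfect per-capita efficiency and zero delay, reproduction is
strictly clonal (no recombination), and there is exactly one detector
and one effector; none of those idealizations hold in real immune
systems.

## Worked example

A deliberately small run (the reference scale is 500 hosts for 500
generations; replicated analyses in this package's own tests use 100
hosts for 150 generations, which preserves the qualitative contrasts at
desk scale):

```{r example, eval = FALSE}
cfg <- simulation_config(infection_chance = 0.9,
                         pleiotropy_mode = "fixed-down",
                         n_hosts = 100, n_generations = 150, seed = 1)
run <- run_coevolution(cfg)
glance(run)
autoplot(response_density(response_profiles(run)$inducibility))
knockout_table(run)
```

Under high infection risk with fixed downregulatory pleiotropy,
populations typically evolve highly *inducible* responses (mean
inducibility near 1): the locked `-1` edge silences constitutive
effector expression, and selection compensates with upregulatory
architecture that fires only after detection. The non-pleiotropic
baseline under the same conditions mostly settles on constitutive
strategies, and at 10% infection risk hosts shed immune investment
almost entirely.

## Known limitations

* The update is an explicit discrete-time map, not an ODE integration;
  step-size artifacts are part of the model definition, not numerical
  error.
* Reference-scale sweeps (100 replicates of 500 x 500 per condition)
  are expensive in R at single-core desk scale; the packaged analyses
  run the scaled-down conditions above and state so.
* The strict-percentile selection rule makes the least-fit survivor
  unable to reproduce except in all-tied pools; with realistic
  fitness spreads this is the intended behavior, but it sharpens
  selection slightly relative to a smooth fitness weighting.
* The `slow` constraint gates mutations at draw time, so the realized
  mutation rate on pleiotropic edges is `rate / 100` only marginally —
  conditional on a mutation having been drawn — exactly as specified,
  but the network-wide mutation rate is unchanged.
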