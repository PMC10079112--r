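# pleiosim

Agent-based simulation of host immune signaling networks coevolving with
signal-manipulating parasites, under four kinds of pleiotropic constraint.

Immune systems balance **constitutive** defense (effectors always on,
always paid for) against **inducible** defense (effectors switched on by
detection). Many immune signaling proteins are *pleiotropic* — they also
serve unrelated traits such as development, which constrains how freely
they can evolve. `pleiosim` is for theoreticians and computational
biologists who want to ask: does that constraint hinder immune network
evolution, or can it push populations toward response strategies (like
inducibility) they would otherwise rarely find?

## The model

A host is a signed digraph of proteins: one detector D, signaling
proteins S (initially three), one effector E; a weight
`w[i,j] ∈ [-1, 1]` upregulates (`k`) or downregulates (`I`) its target;
`D → E` directly is forbidden. Each protein splits into active/inactive
fractions, `[P*] + [P] = 1`, updated synchronously:

    ΔP*_i = [P_i] Σ_j k_ij [P*_j] − [P*_i] Σ_j I_ij [P*_j] − UseCoef · Num(out-edges of i)

Infection adds a parasite node (`+1 → D`, `+0.8` self-replication, a
manipulation edge onto one signaling protein, and `E → parasite` at
`−1`) for at most 20 steps, ending early on clearance (parasite < 1e−2)
or host death (normalized parasite area > 0.9). Host fitness is

    W = exp(−( [E*]pre + V·Area + [E*]post + ProtCost )),
    ProtCost = 1.1·(NetworkSize − 10) above 10 proteins, else 0

Each generation, up to 30% of hosts and parasites die
(fitness-percentile weighted, infection deaths first), survivors
reproduce fitness-weighted back to constant population size, and
offspring rarely mutate (hosts 5e−3: add/delete/reweight an edge,
delete/duplicate a signaling protein; parasites 1e−2: retarget or
reweight). Pleiotropy constrains one signaling protein per host:
`fixed-random` (its initial edges locked forever), `fixed-up` /
`fixed-down` (a locked ±1 edge onto the effector), or `slow` (100×
reduced edge mutation rate).

## Worked example

Fixed downregulatory pleiotropy at 90% lifetime infection risk, at desk
scale (100 hosts, 150 generations):

```r
library(pleiosim)
cfg <- simulation_config(infection_chance = 0.9,
                         pleiotropy_mode = "fixed-down",
                         n_hosts = 100, n_generations = 150, seed = 1)
run <- run_coevolution(cfg)
run
#> <coevolution_run> 100 hosts, 150 generations, infection chance 0.90, mode 'fixed-down'
#>   final: mean fitness 0.933, mean inducibility 1.000, connectivity 0.562
glance(run)
#>   n_generations n_hosts mean_fitness mean_inducibility peak_inducibility
#> 1           150     100        0.933                 1                 1
#>   mean_connectivity mean_network_size frac_cleared frac_dead lineage_split
#> 1             0.562                 7            1         0         FALSE
```

The locked `−1` edge silences constitutive effector expression, and the
population compensates with architecture that fires only after
detection: mean **inducibility** — the induced share of each infected
host's peak effector response, `(peak − pre)/peak` — reaches 1.0, every
final-generation infection is cleared (`frac_cleared = 1`), and mean
fitness is high because hosts pay for effectors only while infected.
Knockouts show which relays the evolved response depends on:

```r
knockout_table(run)
#>   protein pleiotropic divergence
#> 1       2       FALSE      0.000
#> 2       3       FALSE      0.000
#> 3       4        TRUE      0.501
#> 4       6       FALSE      1.000
#> 5       7       FALSE      0.614
```

`divergence` is the mean absolute effector difference over a 20-step
infection between the intact network and the network with that protein
removed: proteins 2–3 are dispensable, while removing protein 6
abolishes the response entirely. `autoplot()` methods draw response
densities, 2D magnitude-vs-inducibility surfaces, and run trajectories;
`run_competition()` pits pleiotropic against non-pleiotropic halves of a
population until one goes extinct; `write_run_archive()` /
`read_run_archive()` persist runs as plain-text archives; a thin CLI
(`inst/cli/pleiosim`) wraps evolve/compete/sweep/analyze/knockout.

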