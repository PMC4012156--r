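# duallattice

Stochastic dual-lattice simulation of how mutualistic symbiosis can evolve
from parasitism when the costs and benefits of the interaction are routed
separately to the two fitness components, **fecundity** and **survival**.
The package is aimed at theoretical ecologists and evolutionary modellers who
want a seeded, scriptable implementation of this model family — mean-field
analysis, spatial Monte-Carlo engine and the standard invasion protocols in
one place.

## The model

Two species inhabit parallel `L x L` toroidal grids and interact only with
the occupant of the same site on the other grid. Every individual is
fundamentally parasitic: it extracts `b'` from its partner and gains `b`. A
*mutualistic* strain additionally pays `c` and delivers `c'`. Each flow is
split between fecundity and survival by an allocation parameter: `p` (own
gain), `q` (partner's loss), `u` (own cost), `v` (partner's gain). For focal
X over an occupied partner Y,

    R = r_X + p_X b_X − q_Y b'_Y  [− u_X c_X]  [+ v_Y c'_Y]
    D = d_X − (1−p_X) b_X + (1−q_Y) b'_Y  [+ (1−u_X) c_X]  [− (1−v_Y) c'_Y]

(bracketed terms when the focal / the partner is a mutualist). Offspring
colonize each empty Neumann neighbour with probability `R/4`; death occurs
with probability `D`.

Two headline results frame the analysis:

* **Unlimited dispersal:** the per-capita growth difference between the
  mutualist and the parasite is `−c (B_P + B_M)(u A_E + 1 − u) ≤ 0` — in a
  well-mixed population a costly mutualist always declines, for every
  parameter value (`selection_differential()`).
* **Limited dispersal:** on the lattice, a rare mutualist introduced at
  frequency 0.04 can invade a parasitic population, but only when
  exploitation is strong and the donation is survival-directed
  (`(p,q) = (0,1)`, `(u,v) = (1,0)`): exploit the partner's fecundity for
  your own survival while donating your fecundity to the partner's survival.

## Worked example

A neutral host (species A, `b = c = 0`) and a symbiont (species B) whose
parasitic wild type exploits `b = 0.2` and whose mutualistic mutant
additionally donates `c = 0.3`:

```r
library(duallattice)
host <- neutral_strain_set()                       # r = 0.5, d = 0.2
symb <- strain_set(parasite_params(b = 0.2),
                   mutualist_params(b = 0.2, c = 0.3))
cfg <- experiment_config(host, symb, targets = "B", replicates = 20, seed = 1)
run_invasion(cfg)
#> invasion_result: mutualist mutants into parasite residents on lattice(s) B
#>   20 replicates, 1000 + 1000 generations, f = 0.04
#>   Sp. B: ensemble-mean mutant frequency 1.0000 -> ESTABLISHED
run_reciprocal(cfg)
#> invasion_result: parasite mutants into parasite/mutualist residents on lattice(s) B
#>   20 replicates, 1000 + 1000 generations, f = 0.04
#>   Sp. B: ensemble-mean mutant frequency 0.0000 -> not established
```

The mutualist sweeps to fixation in every replicate (ensemble mean 1.0,
far above the 0.04 establishment threshold): by donating survival to its
host it keeps its own partners alive, and the host-mutualist clusters
outgrow the parasites. The reciprocal test shows the flip side: parasitic
mutants reintroduced into the established mutualist population die out
(mean 0.0) because each parasite withdraws the donation its own partner
survives on. Invasion and re-invasion are mutually exclusive across the
cost/benefit grid (`parameter_sweep()`).

Other entry points: `mf_integrate()` / `selection_differential()` for the
mean field, `step_generation()` / `introduce_mutants()` for raw lattice
work, `population_ratio()` for host population size relative to a
non-interacting symbiont, `strategy_screen()` for the 16 binary allocation
routings, and a thin CLI (`inst/cli/duallattice.R`) with subcommands
`meanfield | simulate | invade | reciprocal | ratio | screen | sweep` driven
by a YAML config (`inst/examples/host_symbiont.yaml`).

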