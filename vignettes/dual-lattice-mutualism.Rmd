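---
title: "Evolving mutualism from parasitism on a dual lattice: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving mutualism from parasitism on a dual lattice: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duallattice)
```

## The model

Two species, A and B, live on two parallel `L x L` toroidal grids, one
species per grid. An individual interacts only with the occupant of the same
coordinates on the other grid. Each species carries two heritable strains:

* a **parasitic** wild type, which extracts a total resource `b'` from its
  partner and converts it into a gain `b` for itself;
* a **mutualistic** type, which does everything the parasite does *and* pays
  a donation cost `c`, delivering `c'` to its partner.

The model's central device is that every flow is split between the two
fitness components, fecundity and survival, by an allocation parameter in
`[0, 1]`:

| parameter | flow it routes | 1 means | 0 means |
|---|---|---|---|
| `p` | own exploitation gain `b` | own fecundity | own survival |
| `q` | partner's exploitation loss `b'` | partner fecundity | partner survival |
| `u` | own donation cost `c` | own fecundity | own survival |
| `v` | partner's donation gain `c'` | partner fecundity | partner survival |

For a focal individual of species X paired with an occupied partner of
species Y the raw rates are

```
R_raw = r_X + p_X b_X - q_Y b'_Y  [- u_X c_X if focal mutualist]  [+ v_Y c'_Y if partner mutualist]
D_raw = d_X - (1-p_X) b_X + (1-q_Y) b'_Y  [+ (1-u_X) c_X]  [- (1-v_Y) c'_Y]
```

with base rates `(r_X, d_X)` when the partner cell is empty. All interaction
terms require a partner: a mutualist over an empty cell pays nothing and
receives nothing.

### The `u`/`v` routing and the two rate modes

The coefficient formulas in the source literature for this model family print
the *donor's* fecundity split `u_Y` on the recipient's side of the donation,
while the parameter definitions and the verbal model description route the
delivered benefit with `v_Y`. The two disagree only in the term
`(v_Y - u_Y) c'_Y`. We take the `v_Y` routing as the default
(`mode = "corrected"`), because it is the only reading under which the
mutualist-mutualist mortality `d - b + (1-u)c - (1-v)c'` becomes negative
precisely for exploitation `b > 0.1` at `d = 0.2`, `c = c' = 0.1`,
`(u, v) = (1, 0)` — the threshold the model's own analysis reports. The
printed routing is retained verbatim as `mode = "as_printed"` (its crossing
sits at `b = 0.2`) so the consequences of the correction stay auditable:

```{r}
D_mm <- function(b, mode) {
  m <- mutualist_params(b = b, c = 0.1)
  pair_rates(m, "mutualist", m, "mutualist", mode = mode)$D_raw
}
c(corrected = uniroot(D_mm, c(0.001, 0.999), mode = "corrected")$root,
  as_printed = uniroot(D_mm, c(0.001, 0.999), mode = "as_printed")$root)
```

### Clamping

In the spatial model `R` is spread over the four Neumann neighbours
(per-site colonization probability `R/4`) and `D` is a per-event death
probability, so the realized rates are clamped to `R in [0, 4]` and
`D in [0, 1]`. Negative raw mortalities — mutualist pairs at `b > 0.1` —
are clamped to zero rather than rejected: the regime is biologically
implausible (immortal pairs) but it is part of the model's parameter space
and its published analysis, so the engine simulates it and keeps `R_raw`,
`D_raw` available as diagnostics. The mean-field equations, by contrast, use
the **raw** rates throughout: they are the model's analytic object, and the
algebra that proves mutualist decline assumes no clamping.

## Unlimited dispersal: the mean field

With unlimited, random dispersal the six cell-state frequencies
`(A_E, A_P, A_M, B_E, B_P, B_M)` follow a mass-action system
(`mf_derivatives()`). Subtracting per-capita growth rates of the two strains
of species A leaves only the donation-cost terms:

```
(1/A_M) dA_M/dt - (1/A_P) dA_P/dt = -c_A (B_P + B_M) [u_A A_E + (1 - u_A)]
```

which is strictly negative whenever `c_A > 0` and partners exist: **in a
well-mixed population the mutualist always declines, for every parameter
value**. `selection_differential()` returns the direct derivative difference
as its authoritative value and also exposes this closed form alongside an
alternative arrangement, `-c_A [u_A A_E + (1-u_A)(B_P + B_M)]`, that
circulates in print; the latter does not equal the term-by-term difference
but shares its sign, so the impossibility conclusion is insensitive to the
choice. We verify the identity `value == derived form` to `1e-12` on 1,000
random states in the test suite rather than picking one algebra silently.

`mf_integrate()` is a fixed-step explicit Euler scheme (default
`dt = 0.01`, first-order convergence verified in the tests) with a guard:
a component leaving `[0, 1]` by more than `1e-8` aborts with the component's
name. The analysis above is analytic; the integrator exists to make the
decline visible and to provide the single-species benchmark
`A_P -> 1 - d/r` (`equilibrium_occupancy()`), so simplicity and testability
won over adaptive sophistication.

## Limited dispersal: the lattice engine

One *generation* is `L^2` elementary site events at sites drawn uniformly
**with replacement** (some sites update twice per generation, others not at
all; the decay-law test below fixes this convention observably). A site
event, in strict order: the species-A occupant places offspring of its own
strain on each empty Neumann neighbour independently with probability `R/4`;
the species-B occupant does the same; the A occupant dies with probability
`D`; the B occupant dies with probability `D` evaluated against the *current*
A cell — which the previous sub-step may just have emptied. Rates are always
computed from the parent's own partner site, not the offspring's
destination. The inner loop is compiled (C++) but draws all randomness from
R's generator, so a single `set.seed()` reproduces a trajectory bit for bit;
replicated experiments derive one independent substream seed per replicate
(`replicate_seeds()`).

Two analytic anchors pin the engine to the written dynamics:

* with reproduction off (`r = 0`), a full lattice decays in one generation to
  `(1 - d/L^2)^(L^2)` — each individual faces `Binomial(L^2, 1/L^2)` death
  draws;
* a mutant that differs from its resident only by a label (`c = 0`) drifts
  neutrally, so its ensemble-mean frequency stays at the introduction
  frequency.

## The invasion protocol

The standard experiment (`run_invasion()`): fill both grids with wild types,
equilibrate 1,000 generations, introduce mutants at exactly
`round(0.04 L^2)` distinct cells per targeted lattice (replacing whatever is
there — 25 individuals on a 25 x 25 grid), run 1,000 further generations,
record the final mutant frequency over all `L^2` cells, and average over 100
replicates. *Establishment* means the ensemble mean strictly exceeds 0.04:
the mutant population grew beyond its introduced size. Frequencies use all
cells (empty included) as the denominator, matching the mean-field
bookkeeping; the alternative occupied-cells convention is computable from the
same counts.

Replicates whose resident system collapses before the mutants arrive
contribute zero: under heavy fecundity exploitation (`b >= 0.3`, `q = 1`)
the neutral host goes extinct during equilibration, after which the "mutant"
drifts in a dead system and its frequency says nothing about invasion.
Without this rule, neutral drift in collapsed systems produces spurious
establishment calls at high `b`.

`run_reciprocal()` exchanges roles (parasitic mutants into mutualist
residents), `population_ratio()` measures host and symbiont population sizes
against a non-interacting (`b = c = 0`) baseline, `strategy_screen()`
enumerates the 16 binary strategy routings, and `parameter_sweep()` runs the
grid experiments, either over `(b, c)` with a neutral host or along the
symmetric two-species diagonal `b_A = b_B` at fixed `c`.

## Numerical and design choices

* **Strategies are continuous** in `[0, 1]` at the rate level; the binary
  restriction used by the screening experiments lives in the experiment
  layer, not in the rate engine.
* **Symmetry presets** (`b' = b`, `c' = c`, `r = 0.5`, `d = 0.2`) are
  constructor defaults, not constraints; asymmetric exchange (`c' > c`,
  `b' > b`) is reachable by setting fields individually.
* **Neighbour order** (up, right, down, left) is fixed for reproducibility;
  the four colonization draws are independent, so the order is immaterial in
  distribution.
* **Mutant placement** uses sampling without replacement (exactly 25 distinct
  sites), and independent draws per lattice when both species mutate.
* **Sweep grids** default to 0.05 steps because the model's two published
  thresholds (0.1 and 0.15) sit on that grid; grids are arguments, not
  constants.
* **Problem sizes.** The acceptance suite runs the diagonal sweep at 20
  replicates and the neutrality check at 100, with the full 1,000 + 1,000
  generation protocol; unit tests use 150-600-generation runs. These sizes
  put three standard errors of a neutral ensemble mean at roughly 0.015-0.02,
  tight enough to separate establishment (means 0.3-1.0) from drift.

## What the simulations do and do not show

The generator of study conditions here *is* the model: there is no external
data, and every experiment is a function of (parameters, seed). Passing
tests therefore certify internal consistency — the engine implements the
written update rule, the mean field matches its algebra, protocols match
their definitions — not that the model describes any real symbiosis. Real
host-symbiont systems have demographic structure, mutation, intermediate
allocation strategies and environmental variation that the binary-strategy
experiments deliberately exclude.

Two emergent results of this implementation deserve flagging, because they
sharpen (and in places disagree with) the behaviour reported for this model
family. First, wherever the survival channel saturates — clamped zero
mortality — outcomes are dominated by immortal configurations: co-located
mutualist-mutualist pairs at `b >= 0.1` nucleate expanding immortal
clusters, so on the symmetric diagonal at `c = 0.1` mutualism already
establishes at `b = 0.10`, not only from 0.15, and mutualist-mutualist
co-occupancy is common rather than rare once established. Second, a parasite
invading a mutualist population kills the partner whose donation it depends
on and then dies over the empty site, so diagonal re-invasion fails at
*every* grid `b`, not only above 0.1. Both findings were robust to
alternative readings of the update rule (destination-based colonization
rates, permutation site order, disjoint mutant placement) and to the
analytic anchors above, so they appear to be properties of the model as
written rather than artifacts of this implementation. At `b = 0.2` the
resident parasite-parasite world itself freezes (`D = 0`, full lattice), so
establishment there is exactly the introduction frequency and the
established-region is not monotone in `b`.

## Reproducing a run

```{r, eval = FALSE}
sym <- strain_set(parasite_params(b = 0.15), mutualist_params(b = 0.15, c = 0.1))
cfg <- experiment_config(sym, sym, targets = c("A", "B"),
                         replicates = 20, seed = 101)
run_invasion(cfg)
```

Every result object carries its configuration; `write_results()` adds a JSON
sidecar with the seed and rate mode so any table on disk identifies the run
that made it.
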