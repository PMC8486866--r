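---
title: "Model and methods: simulating adaptive radiations in competitive communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: simulating adaptive radiations in competitive communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ecoevorad)
```

`ecoevorad` simulates the adaptive radiation of an asexual consumer lineage
competing for a continuous spectrum of resources along a one-dimensional
ecological trait axis. Diversity is not imposed: species emerge, diversify
and saturate the community as a consequence of frequency-dependent
competition, and an ultrametric phylogeny is a by-product of the branching
history. This vignette documents the model, the simulation algorithm, the
numerical choices, and the package's design decisions and limitations.

## The ecological model

A community is a set of populations (morphs) $i = 1, \dots, n$ with trait
values $z_i$ and abundances $N_i$. Two Gaussian kernels define the
ecology.

**Resource availability.** The carrying capacity of a morph is largest at
the resource optimum $z_{opt}$ (default 0) and falls off with trait
distance:
$$K(z) = K_0 \exp\!\left(-\frac{|z_{opt} - z|^p}{2\,\sigma_K^p}\right),$$
with $p = 2$ (Gaussian) by default; `kernel_exponent` generalizes the
shape (e.g. $p = 4$ gives a flatter-topped, more box-like resource
distribution, used in robustness experiments).

**Competition.** Morphs compete in proportion to their trait similarity:
$$\alpha(z_i, z_j) = \exp\!\left(-\frac{(z_i - z_j)^2}{2\,\sigma_{con}^2}\right),$$
so $\alpha = 1$ for identical traits and decays with trait distance over
the niche width $\sigma_{con}$ — the central parameter of the study
design.

Abundances follow generalized Lotka–Volterra dynamics,
$$\frac{dN_i}{N_i\,dt} = r - r \,\frac{\sum_j \alpha(z_i, z_j)\, N_j}{K(z_i)},$$
i.e. logistic growth toward a carrying capacity discounted by the
competitive load of the whole community.

```{r}
p <- model_params()          # study defaults; see below
carrying_capacity(c(0, 1), p)
competition_coefficient(0, 0.5, sigma_con = 0.5)
```

A single population seeded at the optimum equilibrates at
$K(z_{opt}) = K_0$:

```{r}
solve_equilibrium(community_state(z = 0, N = 1), p)$N
```

## The evolutionary loop

Evolution proceeds by the adaptive-dynamics assumption of time-scale
separation: ecology always reaches equilibrium between rare mutation
events. Each evolutionary step:

1. **Mutation.** One mutant is proposed. The parent population is drawn
   with probability proportional to its abundance (uniform per-capita
   mutation probability $\mu$), and the mutant trait is
   $z' \sim \mathcal{N}(z_{parent}, \sigma_\mu^2)$.
2. **Invasion test.** The mutant's invasion fitness is its initial
   per-capita growth rate while rare in the resident equilibrium
   community:
   $$G(z') = r - r\, \frac{\sum_j \alpha(z', z_j)\, N^*_j}{K(z')}.$$
   If $G(z') \le 0$ the mutant is discarded and nothing changes.
3. **Mutual invasibility.** If the mutant can invade, the mutant is
   swapped in for its parent, the swapped community is brought to
   equilibrium, and the *parent's* invasion fitness is evaluated there.
   If the parent can invade back, the pair is mutually invasible and the
   mutant is **added** (coexistence — the first step of an evolutionary
   branching); otherwise the mutant **replaces** its parent (directional
   trait substitution).
4. **Ecological relaxation.** The community is brought to its new
   equilibrium; populations below the extinction threshold (1 individual)
   are removed.
5. **Species assignment and bookkeeping** (next section).

For a lone resident the selection gradient has the closed form
$-\,(r/\sigma_K^2)\,(z - z_{opt})$: a single lineage always climbs to the
resource optimum. Whether it then branches is decided by the fitness
curvature at the optimum,
$$\left.\frac{\partial^2 G}{\partial z'^2}\right|_{z'=z_{opt}} =
  r\left(\frac{1}{\sigma_{con}^2} - \frac{1}{\sigma_K^2}\right),$$
which is positive (disruptive selection, evolutionary branching point)
exactly when $\sigma_{con} < \sigma_K$, and negative (a stable
evolutionary endpoint) when the niche is wider than the resource
distribution. Both closed forms are exported and verified against
central-difference derivatives of `invasion_fitness()` in the test suite.

```{r}
curvature_at_optimum(model_params(sigma_con = 0.5))   # branches
curvature_at_optimum(model_params(sigma_con = 1.2))   # stays monomorphic
```

### Time

Two clocks are available. The default (`time_model = "step"`) counts one
time unit per evolutionary step, which is the natural scale for
metric-versus-time comparisons across scenarios. The explicit clock
(`time_model = "explicit"`) draws exponentially distributed waiting times
$\Delta t = -\ln(\rho)/w$ with total mutation rate $w = \mu \sum_i N_i$,
making physical time stochastic and abundance-dependent while leaving the
sequence of events unchanged.

## Species, speciation events, and phylogenies

Morphs proliferate by branching, so "species" must be delimited. Two
morphs belong to the same species when they are connected by a chain of
populations with adjacent trait gaps of at most $3 \sigma_\mu$ (a
single-linkage clustering cut: gaps that mutation can plausibly bridge in
one step do not separate species). When a cluster splits, the heavier
fragment keeps the parental species identity and each lighter fragment
becomes a new species; the event is logged as `(time, parent, child)`.

The event log defines the phylogeny of the extant species: divergence
times come from the speciation events, every tip is extant at the present,
and the tree is therefore ultrametric by construction. Patristic distance
uses the two-branch convention, $d(a, b) = 2\,(T - t_{MRCA})$. Trees
export to Newick and round-trip through `ape`.

```{r}
cfg <- simulation_config(model_params(sigma_con = 0.4), n_steps = 400,
                         metric_interval = 200, base_seed = 7)
res <- run_radiation(cfg, replicate = 1)
res
to_newick(res$phylogeny)
```

## Community metrics

Snapshots every `metric_interval` steps record richness and four
distances over extant species — MPD and NNPD (mean and mean
nearest-neighbor patristic distance), MTD and MNTD (mean and mean
nearest-neighbor distance between species mean traits; the species mean
trait is the abundance-weighted mean over member populations) — plus the
Pybus–Harvey $\gamma$ statistic, which summarizes whether internal nodes
are concentrated early ($\gamma < 0$) or late ($\gamma > 0$) in the tree.
Undefined values (fewer than 2 species for distances, fewer than 3 for
$\gamma$) are recorded as missing, never as zero.
`scale_to_baseline()` divides a metric pointwise in time by its
$\sigma_{con} = 0.1$ scenario to compare shapes across niche widths.

```{r}
res$metrics[, c("time", "richness", "MPD", "NNPD", "MTD", "MNTD", "gamma")]
```

## Parameters and problem sizes

| Parameter | Default | Meaning |
|---|---|---|
| `K0` | 10000 | maximal carrying capacity |
| `sigma_K` | 1 | resource-distribution width |
| `sigma_con` | 0.5 | competition niche width (swept 0.1–0.7) |
| `r` | 1 | intrinsic growth rate |
| `mu` | 0.01 | per-capita mutation probability |
| `sigma_mu` | 0.02 | mutational step SD (trait units) |
| `z_opt` | 0 | resource optimum |
| `kernel_exponent` | 2 | resource-kernel shape |
| `extinction_threshold` | 1 | abundance below which a morph is removed |

$\sigma_\mu$ is a standard deviation throughout (the $3\sigma_\mu$
species-gap rule is in trait units).

The full study design (`experiment_preset("study")`) is 5000 evolutionary
steps, metrics every 100 steps, 20 replicates for each of
$\sigma_{con} \in \{0.1, \dots, 0.7\}$; robustness presets vary $r$,
$\sigma_\mu$, the kernel exponent, or the time model around it. A 5000-step
narrow-niche run takes on the order of 10 s on one CPU (about 1 ms per
step at 20–40 morphs), so the full design is roughly an hour of
single-core compute; `run_experiment(..., scale = ...)` shrinks steps and
replicates proportionally for quick passes, and this vignette's examples
use a few hundred steps. Replicate $i$ always runs under seed
`base_seed + i`, and identical configurations reproduce bit-identical
event logs, trees and metric tables.

## Numerical choices

- **Equilibrium.** Because the Gaussian interaction matrix is symmetric
  positive definite, the Lotka–Volterra dynamics admit a quadratic
  Lyapunov function and the stable saturated equilibrium is unique — the
  solution of the non-negative linear complementarity problem
  $A N = K,\ N \ge 0$ on its support. The default solver is a
  Lawson–Hanson-style active-set iteration warm-started from the current
  abundances (one most-violated addition per outer step plus feasibility
  backtracking). Direct ODE integration (`deSolve::lsoda`, `rtol` 1e-10,
  horizon 1000 time units, extended once tenfold if the residual exceeds
  $10^{-6} r$) is the reference route, used as an oracle in the tests and
  as the fallback whenever the active-set route fails; every returned
  state is verified to have per-capita growth below $10^{-6} r$ on all
  surviving morphs.
- **Quasi-neutral twins.** A mutant trait can land within floating-point
  distance of a non-parent resident, making $A$ numerically singular. The
  support solve then falls back to the SVD pseudo-inverse, whose
  minimum-norm solution shares the equilibrium abundance evenly among the
  near-identical morphs — the correct degenerate limit. Symmetrically,
  mutants with invasion fitness at or below $10^{-10} r$ are treated as
  neutral and rejected: such a mutant could only displace its twin on a
  timescale of order $10^{10}$ time units, far beyond any simulated
  horizon, while its presence makes the equilibrium ill-conditioned.
- **Fitness far from the resourced range.** $G(z')$ divides a vanishing
  competition load by a vanishing carrying capacity; both are evaluated in
  log space and combined before exponentiation, so extreme mutants give
  finite fitness instead of 0/0. (Far outside the range, competition
  vanishes faster than $K$, so $G \to r$: such mutants invade but
  equilibrate below the extinction threshold.)
- **$\gamma$.** Implemented directly from the internode-interval formula
  on branching times; the test suite checks it against an independent
  hand-coded evaluation and against `ape::gammaStat`, keeping
  implementation and oracle separate.

## Design decisions

- The mutant is tested against the *swapped* community (mutant in place
  of parent) rather than the grown community, the standard
  adaptive-dynamics protocol for distinguishing substitution from
  branching; the added mutant then starts from abundance 1 and the next
  equilibrium decides who survives.
- Species identity is purely phenotypic (trait-gap clustering of common
  descent); no reproductive isolation is modeled — appropriate for
  asexual lineages.
- When a species splits, abundance decides which fragment keeps the name;
  ties break toward the fragment closer to the parental mean trait.
- The per-step richness trace uses species counts after the step's
  relabeling, so merges (clusters drifting back within $3\sigma_\mu$) are
  visible as richness dips; speciation events are never retroactively
  deleted, and extinct branches are pruned from the exported phylogeny.

## Limitations

- **One trait, one resource axis.** No spatial structure, no sexual
  reproduction, no environmental change; results speak to competition as
  the sole diversifier.
- **Strict time-scale separation.** The community is forced to
  equilibrium between mutations, so transient coexistence and
  drift-driven dynamics are outside the model.
- **Trait-distance ordering at late times.** Early in a radiation, mean
  trait distance (MTD) is larger for wide niches (few, widely spaced
  species); one may expect the ordering to reverse late, once
  narrow-niche communities have packed a broader span of trait space. In
  this implementation the reversal is real but extremely slow: a
  wide-niche community ($\sigma_{con} = 0.6$) reaches its expansion limit
  (edge carrying capacity ≈ competitive load) near $|z| \approx 2.2$,
  while a narrow-niche community can in principle colonize out to where
  $K(z)$ meets the extinction threshold ($|z| \approx 4.3$) — but edge
  populations hold only ~1% of community abundance and therefore receive
  ~1% of mutation events, so diagnostic runs to 20000 steps still show
  wide-niche MTD slightly ahead, with the crossing projected beyond 30000
  steps. At the 5000-step design horizon the early (positive) ordering
  still holds at the final snapshot.
- **Deterministic ecology.** Abundances are continuous; the extinction
  threshold of one individual is the only demographic-stochasticity
  proxy.
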