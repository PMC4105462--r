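---
title: "Knockout strain design with a DE-hybridised bees search: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout strain design with a DE-hybridised bees search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbfba)
```

## The problem

Microorganisms evolve to grow, not to excrete the chemicals we want from
them. Strain design by gene (here: reaction) knockout removes pathways so
that the best remaining way for the cell to grow necessarily co-produces
the target compound. Because genome-scale metabolic models contain
hundreds of candidate reactions, choosing a knockout set is a hard
combinatorial problem; this package couples a population metaheuristic to
flux balance analysis (FBA) to search that space, and certifies candidate
answers with an exact bilevel optimiser.

## Constraint-based model and fitness

A model is a stoichiometric matrix $S \in \mathbb{R}^{m\times n}$ over
metabolites (rows) and reactions (columns), flux bounds
$lb \le v \le ub$ in mmol·gDW⁻¹·h⁻¹, and three designated reactions: the
biomass reaction (whose flux $\mu$ is the growth rate, h⁻¹), a substrate
exchange and a product exchange. FBA solves
$\max c^\top v \;\text{s.t.}\; S v = 0,\; lb \le v \le ub$. A knockout
closes both bounds of a reaction to zero.

Knockout sets are scored by the biomass-product coupled yield,

$$\mathrm{BPCY} \;=\; \frac{v_{\text{product}}\cdot \mu}{v_{\text{substrate}}},$$

evaluated in two LP stages:

1. maximise growth on the knockout model, giving $\mu_{KO}$. The
   viability gate is **strict**: if $\mu_{KO} \le 0.1$ h⁻¹ the mutant
   scores BPCY 0 and is flagged infeasible.
2. otherwise **fix** the biomass flux at a fraction (default 0.9) of
   $\mu_{KO}$ — both bounds, the upper relaxed by $10^{-9}$ for numerical
   head-room — and maximise the product exchange flux. The fixation is
   essential: at 100 % of maximal growth the product flux of an
   uncoupled design is zero (asserted by a test on the branched toy).

The substrate flux in the denominator is the magnitude of the substrate
exchange flux in the *second* (product-maximising) solution. When that
flux is zero with nonzero product the designated substrate cannot be the
carbon source of the product and the evaluation raises a degenerate-yield
error rather than reporting a misleading number. Product maximisation at
fixed growth has a unique optimal *value* even when flux vectors are
degenerate, so only the product value is contractual.

Units: fluxes are mmol·gDW⁻¹·h⁻¹ throughout, so BPCY here is
mmol-based. A gram-based variant would need the product's molar mass;
since no molar masses are part of the model format, the package does not
invent the conversion.

## The search

Genotypes are trait vectors in $[0,1]^d$ over the $d$ deletable
reactions; trait $<$ 0.5 means the reaction is knocked out. This lets
real-valued differential evolution act on binary knockout bees while the
phenotype stays a plain deletion set; changing a trait across 0.5 flips
exactly that one reaction.

One iteration of the loop (`run_dbfba()`):

1. evaluate all `n_scouts` bees (fitness memoised by phenotype, so
   duplicate genotypes cost a single two-stage LP evaluation);
2. select the best sites — `min(m_sites, ceiling(n_scouts/4))` of them,
   ties broken by fewer knockouts then lexicographically so selection is
   deterministic;
3. run `de_generations` rounds of DE restricted to the selected sites:
   donor $x_{r1} + F\,(x_{r2}-x_{r3})$ with distinct partners, clipped to
   $[0,1]$; binomial crossover at rate CR with one forced donor
   coordinate; greedy replacement (never worse). Pools smaller than four
   are padded with singly-perturbed copies that serve as donors only;
4. re-scatter the remaining bees as fresh random scouts.

The best-ever genotype is tracked elitistically (the fitness history is
non-decreasing by construction) and the loop stops at `max_iterations` or
after `convergence_window` iterations without an improvement of at least
$10^{-9}$.

### Parameters

| Parameter | Default | Meaning |
| --- | --- | --- |
| `n_scouts` | 50 | population size |
| `m_sites` | 15 | requested selected sites; the quarter-population cap always applies |
| `F` | 1 | DE mutation factor, in [0, 2] |
| `CR` | 0.5 | DE crossover probability |
| `de_generations` | 5 | DE rounds per bees iteration |
| `ko_init_prob` | `min(0.5, 3/d)` | per-reaction knockout probability at initialisation |
| `max_knockouts` | 5 | cap on knockouts per initial/scout bee |
| `growth_threshold` | 0.1 h⁻¹ | strict viability gate |
| `growth_fraction` | 0.9 | growth fixation before product maximisation |

`m_sites = 15`, `F = 1` and `CR = 0.5` are the tuned values of the
method; the quarter-population cap on selected sites is taken as binding
whenever it is smaller than `m_sites` (with the default population of 50
the effective site count is 13). `de_generations` is this package's own
choice: five rounds keep the per-iteration budget of the DE stage
(sites × 5 trials) comparable to the classic neighbourhood it replaces.
`ko_init_prob` defaults to about three knockouts per initial bee — the
scale of knockout set these searches target — but is capped at 0.5
because on small spaces ($d \le 6$) the uncapped ratio would approach or
exceed 1 and every bee would start with *all* reactions deleted, a
deterministic and nonviable initialisation; 0.5 is the unbiased coin.
Initial bees exceeding `max_knockouts` have randomly chosen knockouts
re-flipped to present.

### The classic-BA comparison variant

`run_ba()` swaps the DE stage for the classic neighbourhood: each
selected site receives `ba_recruits = 5` uniform samples within a patch
of radius `ba_ngh = 0.1` (trait units), keeping the best. The patch
radius is **fixed** by default (`ba_shrink = 1`): the classic bees
algorithm uses a constant patch size, and a shrinking radius (available
via `ba_shrink < 1`) turns the variant into a fine-grained local search
that no longer represents the baseline being compared against. On the
smooth 2-D benchmarks the two variants reach the same plateaus; the DE
variant's advantage shows in final precision where exact convergence is
achievable (e.g. Martin & Gaddy), and that is the comparison the test
suite asserts. On De Jong at the study budget both variants' means agree
to ~$10^{-6}$ relative and their ordering is seed-dependent, so no test
pretends otherwise.

## Benchmark harness

Four standard test functions, all stated in maximisation sense (the
classic minimisation forms inverted): De Jong
$3905.93 - 100(x_1^2-x_2)^2 - (1-x_1)^2$ on $[-2.048, 2.048]^2$ (maximum
3905.93 at (1,1)); Martin & Gaddy (negated) on $[0,10]^2$ (maximum 0 at
(5,5)); Branin (negated, a = 1, b = 5.1/4π², c = 5/π) on
$[-5,10]\times[0,15]$ (maximum −0.397887); Griewank (negated, 2-D by
default) on $[-100,100]^2$ (maximum 0). `run_trials()` executes 100
independent runs with per-run seeds derived from one master seed and
reports the mean and the *population* (divide-by-N) standard deviation of
the per-run best objective — the statistics conventionally quoted for
this family of methods. `scripts/acceptance.R` reproduces that study:
50-iteration runs for De Jong, 100-iteration runs for Martin & Gaddy,
population 50, no early stopping.

## Pre-processing

`reduce_model()` prepares a model for search:

* **Blocked (dead-end) reactions** — reactions whose FVA range is
  [0, 0] — are removed, along with metabolites left orphaned. FVA runs
  with the exchange bounds *as given by the model file*, not forced open:
  the file's medium is part of the design problem, and opening exchanges
  would unblock reactions that can never carry flux under the actual
  growth condition.
* **Essential reactions** — single deletions that drop maximal growth to
  at most the 0.1 h⁻¹ gate (the same gate as the fitness pipeline) — are
  **protected** from knockout rather than deleted: they are perfectly
  functional in the wild type, and removing them would change wild-type
  behaviour. A solution containing an essential deletion would be
  invalid, so the search simply cannot propose one.
* Exchanges, the biomass reaction and user-listed reactions are likewise
  protected. Reduction is idempotent and provably leaves wild-type
  maximal growth and maximal product unchanged (asserted to $10^{-6}$).

## Exact validation (bilevel MILP)

The bilevel program — outer maximisation of the product rate over
knockout binaries $y$ ($y_j = 0$: knocked out, at most $K$ zeros), inner
growth-maximising FBA — is collapsed to one MILP by replacing the inner
LP with its optimality conditions: primal feasibility, dual feasibility
with big-M deactivation of knocked-out columns
($|S_j^\top\lambda + \mu^u_j - \mu^l_j - c_j| \le M(1-y_j)$), the strong
duality equality, bound coupling $lb_j y_j \le v_j \le ub_j y_j$, a
growth floor, and linearisation variables $z = y\,\mu$ for the bilinear
dual-objective terms. $M$ defaults to twice the largest absolute flux
bound and also bounds the dual variables.

With no MILP (or production LP) solver available in the dependency
stack, the package carries its own machinery:

* **LP core**: a two-phase dense tableau simplex with Bland's
  anti-cycling rule. Before solving, variables pinned by their bounds
  (knocked-out reactions, the fixed biomass flux) are substituted out and
  constraint rows emptied by the substitution are checked and dropped —
  FBA knockout LPs are degenerate in exactly this way, and textbook
  simplex implementations fail on them without the clean-up.
* **Branch and bound** on $y$: LP-relaxation bounds, most-fractional
  branching, keep-branch first. Integral incumbents are re-scored by the
  direct two-stage LP evaluation of the bilevel objective, so reported
  rates are exact and carry no big-M artefacts; the relaxation is used
  only for pruning. A $10^{-6}$ objective penalty per knockout prefers
  smaller sets among equal-rate optima. The duality gap of the inner LP
  at the returned solution is re-checked by an explicit dual solve.

`validate_solution()` accepts a heuristic design when its value is within
a **strict** 0.001 of the MILP optimum. Two comparison modes exist
because a BPCY (per-substrate, growth-weighted) and a raw production rate
are dimensionally different quantities: the default `product_rate` mode
clamps the biomass upper bound to the heuristic's fixed growth so that
both numbers are product fluxes at the same growth, which makes the
0.001 criterion meaningful; the `bpcy` mode performs the literal
BPCY-versus-rate comparison as historically described, and is expected to
reject except where the two scales happen to coincide. The MILP's
candidate set defaults to *all* deletable reactions (not just the
heuristic's picks), so validation really asks "is there any equally-sized
design that beats this one at this growth?".

## Synthetic fixtures and what they do (not) show

`make_branched_model()` builds the test universe: a substrate exchange
(bound 10) feeding a hub with a biomass branch, a product branch and
competing drains. With `byproduct = TRUE` an alternative biomass route
co-produces a by-product convertible to product; knocking out the
efficient route then raises the coupled yield (wild type BPCY 0.9,
planted optimum 2.475 via deletion of `BIO`). This construction is used
deliberately: under growth-maximising FBA, pure linear branch competition
never rewards a knockout — the LP already routes spare substrate
optimally — so a non-trivial optimum requires growth-coupled by-product
forcing, which is the same mechanism that makes real strain design work.
Exhaustive oracles (`brute_force_knockouts()`, `brute_force_bilevel()`,
guarded at 15 deletable reactions) provide ground truth for every search
and MILP test, and an independent LP implementation (scipy's HiGHS,
driven through a subprocess) re-computes the full fitness table in the
test suite as a cross-solver check.

What the toys do **not** emulate: genome-scale dimensionality (search
spaces here have 2–7 deletable reactions, so a passing search test shows
correctness of the machinery, not search power at $d \approx 600$);
cofactor/energy coupling and redundancy structure of real networks; any
units beyond mmol-based fluxes. Reproducing published genome-scale case
studies additionally requires the model files and their (unstated)
substrate-uptake conditions, which is why the package treats those as
external inputs: `read_model()` accepts any SBML L3+FBC or BiGG JSON
file, and substrate/product/biomass designations are explicit arguments
precisely because no file format carries them reliably.

## Numerical choices

* Simplex pivot tolerance $10^{-9}$; phase-1 feasibility accepted below
  $10^{-7}$; mass-balance residuals of optimal solutions asserted below
  $10^{-6}$ in tests.
* Bounds are finite by construction; files omitting bounds get ±1000
  (the community convention), so the LPs cannot be unbounded.
* Growth fixation uses $[0.9\mu,\; 0.9\mu + 10^{-9}]$; the pinned-column
  substitution then treats the biomass flux as fixed at $0.9\mu$ exactly.
* Selection and oracle orderings break ties deterministically (fewer
  knockouts, then lexicographic), so equal seeds reproduce equal results
  bit-for-bit; every stochastic entry point takes or records a seed.
* Problem sizes in the default test run: toys up to 13 reactions,
  enumeration up to $K = 3$, 20-seed search repetitions, and the
  100-run benchmark study at its stated budgets (50/100 iterations).

## Known limitations

* The simplex is dense and pure R: adequate for toys and for
  medium-sized models, but a genome-scale search (hundreds of reactions,
  thousands of LP evaluations) wants a compiled solver behind the same
  `lp_solve()` interface.
* Knockouts act at reaction level; gene–protein–reaction logic (one gene
  disabling several reactions, isozymes rescuing one) is out of scope.
* The MILP's big-M and dual bounds are finite constants; pathological
  models with dual multipliers exceeding them would need the exported
  `big_M` argument raised. The branch-and-bound node cap returns the
  incumbent with status `"time_limit"` rather than failing.
* Only growth maximisation is supported as the inner objective;
  MOMA/ROOM-style knockout phenotype predictions and parsimonious or
  loopless FBA are non-goals.
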