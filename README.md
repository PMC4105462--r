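# dbfba — DE-hybridised bees search over flux balance analysis

`dbfba` designs microbial production strains *in silico*: given a
constraint-based (stoichiometric) metabolic model, it searches for sets of
reaction knockouts that force the organism to over-produce a target
metabolite while still growing. It is aimed at metabolic engineers and
systems biologists who work with genome-scale models in SBML (Level 3 +
FBC) or BiGG-style JSON and want a heuristic knockout search whose answers
can be certified against an exact bilevel optimiser.

## The model and the score

Cellular metabolism at steady state is the linear system **S·v = 0** with
flux bounds **lb ≤ v ≤ ub**, where **S** is the m × n stoichiometric
matrix. Flux balance analysis (FBA) predicts behaviour by solving the LP

max **c**ᵀ**v**  s.t.  **S·v** = 0, **lb** ≤ **v** ≤ **ub**

with **c** selecting the biomass reaction. A knockout sets both bounds of
a reaction to zero. Candidate knockout sets are scored by the
**biomass-product coupled yield**

BPCY = (v_product · μ) / v_substrate,

computed in two LP stages: maximise growth on the knockout model (mutants
with μ ≤ 0.1 h⁻¹ score zero — not viable); then pin the biomass flux at
90 % of that optimum and maximise the product exchange flux (at 100 % of
maximal growth the product flux is typically zero, which is why the
fixation is needed).

The search itself is a bees algorithm whose neighbourhood stage is
differential evolution (DE): scout bees (binary knockout genotypes encoded
as trait vectors in [0,1]ᵈ, binarised at 0.5) are evaluated, the best
sites — at most *m* = 15 and never more than a quarter of the population —
evolve by DE (donor = x_r1 + F·(x_r2 − x_r3), F = 1, binomial crossover
CR = 0.5, greedy replacement), and the remaining bees re-scatter at
random. Solutions are validated by re-solving the design exactly: a
bilevel program (outer product maximisation over knockouts, inner
growth-maximising FBA) collapsed to a single MILP through LP strong
duality and solved by branch and bound; a heuristic solution is accepted
when it comes within 0.001 of the bilevel optimum.

## Worked example

The built-in branched toy plants a knockout optimum: an efficient biomass
route competes with a less efficient one that co-produces a by-product
convertible to product, so deleting the efficient route couples production
to growth.

```r
library(dbfba)

model <- make_branched_model(4, byproduct = TRUE)
model
#> Metabolic model 'branched_toy_4b_byp': 7 metabolites, 13 reactions (7 deletable)
#>   biomass:   BIOMASS
#>   substrate: EX_glc
#>   product:   EX_P

red <- reduce_model(model)          # blocked-reaction removal, essentiality screen
res <- run_dbfba(red$model, optimizer_config(n_scouts = 30, seed = 7))
res
#> Bees search result (seed 7): best fitness 2.475 after 20 iterations, 119 evaluations
#>   knockouts: BIO, WDRAIN

fit <- evaluate_knockout_fitness(red$model, res$knockout_ids)
fit
#> Knockout fitness: growth 4.5 /h, product 5.5 mmol/gDW/h, yield 0.55, BPCY 2.475

validate_solution(red$model, res$knockout_ids, fit)
#> Validation (product_rate): heuristic 5.5 vs bilevel optimum 5.5, |difference| = 1e-09 -> VALID
```

The wild type scores BPCY 0.9; the search finds the planted deletion of
the efficient biomass route `BIO` (plus a harmless waste-drain knockout),
raising the coupled yield to 2.475, and the bilevel MILP certifies that no
design with the same knockout budget does better at that growth.

The same steps are available from a shell:

```sh
Rscript inst/cli/dbfba.R fixtures --out fixtures/
Rscript inst/cli/dbfba.R optimize fixtures/branched.json --seed 7 --out result.json
Rscript inst/cli/dbfba.R validate fixtures/branched.json result.json
Rscript inst/cli/dbfba.R benchmark --function dejong --algo db --runs 100 --seed 1 --out table.csv
```

## Package layout

| Area | Functions |
| --- | --- |
| Model container & I/O | `metabolic_model()`, `reaction()`, `read_model()`, `write_model()`, `stoichiometric_matrix()`, `apply_knockouts()` |
| FBA & fitness | `solve_fba()`, `evaluate_knockout_fitness()`, `production_yield()`, `bpcy()` |
| Pre-processing | `find_dead_end_reactions()`, `find_lethal_reactions()`, `reduce_model()` |
| Search | `optimizer_config()`, `run_dbfba()`, `run_ba()`, `knockout_space()` |
| Exact validation | `solve_optknock()`, `validate_solution()`, `write_optknock_lp()` |
| Benchmarks | `make_benchmark()`, `run_trials()` |
| Synthetic fixtures & oracles | `make_chain_model()`, `make_branched_model()`, `brute_force_knockouts()`, `brute_force_bilevel()` |

See `vignettes/strain-design-methods.Rmd` for the full account of the
method, its parameters and its limitations.
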