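# emdesign

Strain design for small metabolic networks from elementary flux modes,
pathway thermodynamics, and genetic algorithms.

## The problem

Microbial production strains face a built-in conflict: cells have evolved to
grow, not to excrete a product of interest, so the flux states that maximize
product yield are usually far from the ones a wild-type network settles
into. Choosing which reactions to knock out so that the remaining network is
*forced* towards product formation — while still making biomass — is a
combinatorial search over genotypes that grows as 2^n in the number of
reactions, intractable to enumerate even for central-metabolism-sized
models.

`emdesign` implements a design loop that needs nothing beyond network
stoichiometry, reversibility, and (optionally) standard Gibbs energies:

1. **Elementary flux modes.** The elementary modes (EMs) of a stoichiometric
   model are the support-minimal steady-state flux vectors: `S e = 0` over
   the internal metabolites, `e_j >= 0` on irreversible reactions, and no
   steady-state vector has a support strictly inside theirs. They are the
   extreme rays of the flux cone; every achievable flux state is a
   nonnegative combination of them. `enumerate_efms()` computes the complete
   set by the double-description method (reversible reactions split into
   irreversible pairs, spurious two-cycles removed); `brute_force_efms()` is
   an independent exhaustive oracle for small networks.
2. **Flux reconstruction by EM weighting.** A flux distribution is
   reconstructed as `v = M c`, where the columns of `M` are the modes
   (normalized to unit substrate uptake) and `c` is a weight vector with
   `sum(c) = 1`. Two weighting policies are provided: uniform weights
   (`equal_weights()`), and thermodynamic weights
   (`thermo_weights()`), `c_i ∝ exp(-ΔGp°_i / RT)` with
   `R = 1.9872e-3 kcal/mol/K`, `T = 310.15 K` by default, where
   `ΔGp°_i = Σ_j e_ij ΔGr°_j` is the pathway standard Gibbs energy of mode
   *i*. Modes with `ΔGp° > 0` are thermodynamically infeasible and receive
   weight exactly zero.
3. **Knockout search.** A strain is a binary chromosome over the deletable
   reactions (essential reactions — those whose single removal drives the
   maximal product or biomass yield to zero, `essential_reactions()` — are
   fixed to 1). Its fitness is the reconstructed product yield and/or
   biomass yield as a fraction of the parent's theoretical (best-mode)
   yields: product fraction, biomass fraction, or their product ("coupled").
   `run_ga()` evolves chromosomes with two-point crossover, uniform
   mutation, tournament or roulette selection and elitism;
   `run_moga()` is an NSGA-II-style controlled-elitist variant returning
   the Pareto front of (product fraction, biomass fraction);
   `exhaustive_search()` is the brute-force oracle.
4. **Baselines.** `fba_fluxes()` solves the flux balance analysis linear
   program (maximize an objective flux subject to `S v = 0` and bounds, with
   substrate uptake fixed to 1) for comparison with EM-weighted fluxes.

Everything takes and returns plain data frames/tibbles where tabular;
results have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(emdesign)

model <- toy_fixture("TOY-ETHANOL")   # glucose -> 2 ethanol + 2 CO2, biomass branch
ems   <- enumerate_efms(model)
tidy(ems, model)
#> # A tibble: 2 × 7
#>    mode substrate_flux product_flux biomass_flux product_yield_mass ...
#> 1     1              1            2            0              0.511
#> 2     2              1            0            1              0
```

The first mode is the homoethanologenic route: per mole of glucose it makes
2 moles of ethanol, i.e. `2 × 46.069 / 180.156 = 0.511` g ethanol per g
glucose — the theoretical mass yield. The second is the biomass branch.

```r
coupled <- toy_fixture("TOY-COUPLED")
res <- run_ga(coupled, ga_config(fitness = "coupled", population_size = 20,
                                 max_generations = 40, rng_seed = 1))
res
#> <ga_result> model TOY-COUPLED, fitness = 0.25 (coupled, equal weighting)
#>   26 generations, 10 strain evaluations, 4 reactions removed
res$best$removed_reactions
#> [1] "LOW" "WA"  "WB"  "CYC"
```

The GA removes the two waste sinks, the diversion route and the internal
cycle, leaving only the product and biomass modes: both yield fractions are
0.5, so the coupled fitness is 0.25 — which `exhaustive_search()` confirms
is the global optimum for this network.

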