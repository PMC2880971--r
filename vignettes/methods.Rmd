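---
title: "Methods: elementary-mode strain design with thermodynamic weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elementary-mode strain design with thermodynamic weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdesign)
```

## The model

A stoichiometric model is a matrix $S$ (one row per *internal* metabolite,
one column per reaction), reversibility flags, and three designated
reactions: substrate uptake, product formation, and biomass synthesis.
External metabolites (suffix `_ext` in the TSV dialect) are sources and
sinks; they never constrain the steady state. The core steady-state
assumption is $S v = 0$ with $v_j \ge 0$ on irreversible reactions: the
feasible flux states form a polyhedral cone.

The **elementary flux modes** (EMs) are the support-minimal elements of that
cone — equivalently, after splitting each reversible reaction into an
irreversible forward/backward pair, its extreme rays. Every achievable flux
state is a nonnegative combination of EMs, which is what makes them a
complete, assumption-free description of what a genotype *can* do. We
enumerate them with the classical double-description scheme: the tableau
starts from the identity over (split) reactions, metabolites are processed
one at a time, rays violating the new balance are combined pairwise across
signs, and candidates whose support strictly contains another ray's support
are discarded. Forward+backward two-cycles of a reversible reaction are
spurious and removed at the end; surviving modes are folded back to signed
coefficients on the original reactions. Faster tree-structured
implementations of the same enumeration exist; completeness, not speed, is
the property we verify, via `brute_force_efms()`, which independently tests
every candidate support for a one-dimensional, sign-feasible nullspace.

## Flux reconstruction and weighting

A flux distribution is reconstructed as $v = M c$ where the columns of $M$
are modes and $\sum_i c_i = 1$. Two policies:

* **equal**: $c_i = 1/n$. A deliberately assumption-free baseline.
* **thermodynamic**: each mode's pathway standard Gibbs energy is the
  coefficient-weighted sum of its reaction energies,
  $\Delta G_p^\circ = \sum_j e_j \Delta G_r^\circ{}_j$ (a reversible
  reaction used backwards contributes the negated value), and
  $c_i \propto \exp(-\Delta G_p^\circ{}_i / RT)$ for feasible modes, with
  $c_i = 0$ exactly when $\Delta G_p^\circ{}_i > 0$ (thermodynamically
  infeasible). The exponential (Boltzmann) form is the canonical
  "log-weight linear in pathway free energy" choice; it is isolated behind
  `thermo_weights()` so an alternative monotone form could be swapped
  without touching callers. Equal weighting deliberately does **not** zero
  infeasible modes — infeasibility filtering is part of the thermodynamic
  policy only.

Parameters, units, defaults: Gibbs energies are kcal/mol throughout
($\Delta G_f^\circ$ per metabolite in, $\Delta G_r^\circ$ per reaction
derived or supplied directly, the latter taking precedence);
$R = 1.9872 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$; $T = 310.15$ K
(37 °C, optimal *E. coli* growth) by default. Currency metabolites absent
from $S$ still enter the energy bookkeeping when reactions are written with
their full stoichiometry.

Three numerical conventions matter here:

* **Mode scale.** The exponent in the Boltzmann weight is scale-sensitive,
  so $\Delta G_p^\circ$ is computed on modes normalized to **unit substrate
  uptake** — the only scale already fixed by the yield convention. Modes
  with no substrate uptake (internal cycles) are normalized to maximum
  absolute coefficient 1; they participate in weighting but contribute zero
  to yields.
* **Overflow.** Exponents are shifted by their maximum before
  exponentiation; the shift cancels in the normalization.
* **Yields.** The product yield is a mass yield,
  $(v_{product} \cdot MW_{product}) / (v_{substrate} \cdot MW_{substrate})$;
  biomass is reported as biomass-reaction flux per unit substrate. Fluxes of
  the *designated* reactions alone count: a species reaching the product
  pool through another reaction (or a deliberately unbalanced product, as
  with a heterologous pigment not balanced in its synthesis reaction) is
  scored via the designated reaction's flux. Strain-level yields are the
  weight-averaged per-mode yields, which coincide with yields of the
  reconstructed $v$ whenever every weighted mode consumes substrate.

## Knockout search

A strain is a binary chromosome over the *deletable* reactions. The
essentiality pre-screen removes from the search every reaction whose single
deletion drives the maximal product **or** biomass yield to zero; these are
fixed to 1. Fitness is computed against the **parent's** theoretical yields
(denominators fixed across strains, so fractions are comparable):
product fraction, biomass fraction, or their product ("coupled", which
scores zero for any strain that lost either capability).

Two properties make evaluation cheap and exact:

* **Knockout-subset property.** The EM set of a deletion strain is exactly
  the subset of parent modes whose supports avoid the removed reactions.
  Strains are therefore scored by filtering the parent's modes rather than
  re-enumerating; the equivalence is asserted against re-enumeration on
  fixtures and random networks in the test suite.
* **Caching.** Evaluations are cached by genotype, so a converged GA
  population costs almost nothing per generation.

GA defaults (all configurable in `ga_config()`): population 50, 5 elites,
initial genotypes seeded with 2–6 knockouts (seeding near the wild type
keeps the initial population mostly viable; seeding at ~50% zeros yields
mostly dead strains), two-point crossover at rate 0.8, uniform per-bit
mutation at 0.01, tournament (size 2) or roulette selection, termination on
a relative best-fitness change below $10^{-6}$ sustained for 25 generations
or at 100 generations. The multi-objective variant (`run_moga()`) maximizes
(product fraction, biomass fraction) with fast non-dominated sorting,
crowding-distance diversity and controlled elitism capping the first
front's share of each generation at 0.35 of the population (the mechanism
is standard; the cap value is a package choice, tunable via
`pareto_fraction`); population 200 is the conventional size, and a
generation cap replaces the stall rule because front convergence has no
scalar stall criterion. Both optimizers expose `rng_seed`; identical seeds
reproduce identical runs.

`fba_fluxes()` provides the linear-programming baseline: maximize one flux
subject to $S v = 0$, default bounds $[-10, 10]$ (reversible) / $[0, 10]$
(irreversible), substrate fixed to 1. With uptake fixed and capacity bounds
non-binding the LP optimum equals the best per-substrate yield over the
EMs — a cross-module identity the tests exploit. Degenerate alternate
optima exist in general; one solver vertex is reported.

## Fixtures and the random-network generator

The fixture catalogue (`toy_fixture()`) contains four networks whose
complete EM sets are documented and brute-force-verifiable: a two-branch
network (2 modes), a reversible chain whose two-cycle must be excluded
(1 mode), an 8-reaction coupled-design network with 6 modes, distinct
product/biomass routes, waste sinks, an internal cycle and a known global
coupled optimum (fitness 0.25 after 4 removals), and a toy ethanol network
carrying real molecular weights so the analytic theoretical yield
$2 \times 46.069 / 180.156 = 0.511$ g/g is reproduced exactly.

`random_toy_model()` generates property-test networks: 2–4 internal
metabolites, up to 12 reactions, random conversions some of which are
reversible. Each internal metabolite carries an implicit mass of
$2^{n-i}$ and conversion coefficients conserve that mass, so the networks
cannot create product out of nothing — without this, random stoichiometries
routinely contain mass-amplifying loops that break the LP/EM-yield identity
and have no biological counterpart. What these networks *do not* emulate:
realistic pathway lengths, cofactor coupling, or the mode-count explosion
of central metabolism (the reference case studies have $10^4$–$10^5$
modes). Passing tests therefore certify algorithmic correctness at oracle
scale, not performance at model scale.

Problem sizes used by the test and acceptance runs: all four fixtures,
50 (tests) / 20 (acceptance script) random networks of up to 12 reactions,
10-seed GA replicates, and exhaustive searches over up to $2^5$ genotypes.

## Numerical choices

Stoichiometric coefficients are stored as doubles; rank and nullity
decisions (elementarity, nullspace dimension) use SVD/QR with tolerance
$10^{-9}$, which is exact in effect for the small-integer stoichiometries
in scope. Mode vectors are cleaned by continued-fraction rational rounding
(denominator limit $10^6$) before normalization, snapping float artefacts
like 0.333333331 back to 1/3. "Produces X" means a designated-reaction
coefficient above $10^{-9}$ after normalization. Ties in `max_yield()` are
resolved by reporting *all* attaining modes within relative tolerance
$10^{-6}$, in deterministic support-lexicographic order. Degenerate strains
(no surviving modes; all survivors infeasible under thermodynamic
weighting) score 0 rather than erroring, so optimizers can traverse them.

## Known limitations

* EM enumeration is exponential in network size; the implementation targets
  small-scale (central-metabolism) models, not genome scale.
* Standard-state energies ($\Delta G^\circ$, 1 M, pH 7) are first-order
  approximations; no activity/concentration corrections are applied.
* Gene–reaction mapping is one-to-one; no many-to-many GPR logic, no
  overexpression or insertion moves — the search is knockout-only.
* No regulatory information: steady-state stoichiometry only.
* The FBA comparison reports a single optimal vertex; reaction-wise
  comparisons should keep alternate-optima degeneracy in mind.
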