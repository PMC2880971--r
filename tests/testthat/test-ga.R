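test_that("GA configuration is validated", {
  expect_error(ga_config(population_size = 10, elite_count = 10))
  expect_error(ga_config(mutation_rate = 2))
  expect_error(ga_config(initial_knockouts_range = c(6, 2)))
  cfg <- ga_config(fitness = "product", weighting_scheme = "thermodynamic")
  expect_s3_class(cfg, "ga_config")
  expect_equal(cfg$population_size, 50L)
  expect_equal(cfg$elite_count, 5L)
  expect_equal(cfg$initial_knockouts_range, c(2L, 6L))
})

test_that("essential reactions are those whose removal kills product or biomass", {
  m <- toy_fixture("TOY-BRANCH")
  expect_true("UPT" %in% essential_reactions(m))

  m <- toy_fixture("TOY-COUPLED")
  # UPT feeds everything; ISO is the only route to B (hence biomass);
  # PRD/BIO are the designated product/biomass reactions themselves
  expect_setequal(essential_reactions(m), c("UPT", "ISO", "PRD", "BIO"))
})

test_that("strain evaluation honours knockouts, weighting and degeneracy", {
  m <- toy_fixture("TOY-COUPLED")
  cfg <- ga_config(fitness = "coupled")
  ctx <- strain_context(m, cfg)
  n_var <- length(ctx$deletable)

  # wild type: all six modes survive, fractions 1/6 each
  wt <- evaluate_strain(rep(1L, n_var), ctx)
  expect_equal(wt$n_modes, 6L)
  expect_equal(wt$product_fraction, 1 / 6, tolerance = 1e-9)
  expect_equal(wt$biomass_fraction, 1 / 6, tolerance = 1e-9)
  expect_lt(wt$coupled, 1)

  # removing every deletable reaction leaves the two designated routes
  none <- evaluate_strain(rep(0L, n_var), ctx)
  expect_equal(none$n_modes, 2L)
  expect_equal(none$fitness, 0.25, tolerance = 1e-9)

  expect_error(evaluate_strain(rep(1L, n_var + 1), ctx), "chromosome length")

  # degenerate strain: all surviving modes infeasible scores 0
  tt <- flat_thermo(m, +1)
  cfg_t <- ga_config(fitness = "coupled", weighting_scheme = "thermodynamic")
  ctx_t <- strain_context(m, cfg_t, thermo = tt)
  z <- evaluate_strain(rep(1L, n_var), ctx_t)
  expect_equal(z$fitness, 0)
})

test_that("fitness fractions are bounded and coupled is their product", {
  set.seed(17)
  m <- toy_fixture("TOY-COUPLED")
  ctx <- strain_context(m, ga_config(fitness = "coupled"))
  n_var <- length(ctx$deletable)
  for (i in 1:20) {
    bits <- sample(0:1, n_var, replace = TRUE)
    r <- evaluate_strain(bits, ctx)
    expect_gte(r$product_fraction, 0); expect_lte(r$product_fraction, 1)
    expect_gte(r$biomass_fraction, 0); expect_lte(r$biomass_fraction, 1)
    expect_equal(r$coupled, r$product_fraction * r$biomass_fraction)
    expect_lte(r$coupled, min(r$product_fraction, r$biomass_fraction) + 1e-12)
  }
})

test_that("mode filtering equals re-enumeration of the knocked-out submodel", {
  m <- toy_fixture("TOY-COUPLED")
  ems <- enumerate_efms(m)
  protected <- essential_reactions(m, ems)
  deletable <- setdiff(m$reactions$id, protected)
  set.seed(5)
  for (i in 1:5) {
    bits <- sample(0:1, length(deletable), replace = TRUE)
    removed <- deletable[bits == 0]
    filtered <- surviving_modes(ems, removed)
    sub <- apply_knockouts(m, bits, protected)
    expect_setequal(support_strings(filtered),
                    support_strings(enumerate_efms(sub)))
  }
})

test_that("GA reaches the exhaustive optimum on the coupled fixture", {
  m <- toy_fixture("TOY-COUPLED")
  cfg0 <- ga_config(population_size = 20, max_generations = 40,
                    fitness = "coupled")
  ctx <- strain_context(m, cfg0)
  opt <- exhaustive_search(m, max_knockouts = length(ctx$deletable),
                           cfg = cfg0, context = ctx)
  expect_equal(opt$record$fitness, 0.25, tolerance = 1e-9)
  expect_setequal(opt$removed_reactions, c("LOW", "WA", "WB", "CYC"))

  for (seed in 1:10) {
    cfg <- ga_config(population_size = 20, max_generations = 40,
                     fitness = "coupled", rng_seed = seed)
    res <- run_ga(m, cfg, context = ctx)
    expect_equal(res$best$record$fitness, opt$record$fitness,
                 tolerance = 1e-9)
  }
})

test_that("elitism makes the best fitness non-decreasing", {
  m <- toy_fixture("TOY-COUPLED")
  cfg <- ga_config(population_size = 16, max_generations = 30, rng_seed = 3,
                   fitness = "coupled", mutation_rate = 0.05)
  res <- run_ga(m, cfg)
  expect_true(all(diff(res$history$best_fitness) >= 0))
})

test_that("a seeded optimum is retained under elitism with no variation", {
  m <- toy_fixture("TOY-COUPLED")
  cfg <- ga_config(population_size = 10, elite_count = 2, mutation_rate = 0,
                   crossover_rate = 0, max_generations = 10, rng_seed = 9,
                   fitness = "coupled")
  ctx <- strain_context(m, cfg)
  res <- run_ga(m, cfg, context = ctx)
  # with no mutation/crossover the run cannot lose its best seed
  first_best <- res$history$best_fitness[1]
  expect_true(all(res$history$best_fitness == first_best))
})

test_that("identical seeds reproduce identical histories", {
  m <- toy_fixture("TOY-COUPLED")
  ctx <- strain_context(m, ga_config(fitness = "coupled"))
  cfg <- ga_config(population_size = 14, max_generations = 15, rng_seed = 77,
                   fitness = "coupled", mutation_rate = 0.05)
  r1 <- run_ga(m, cfg, context = ctx)
  r2 <- run_ga(m, cfg, context = ctx)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best$chromosome, r2$best$chromosome)
})

test_that("exhaustive search respects its budget and the zero-knockout case", {
  m <- toy_fixture("TOY-COUPLED")
  cfg <- ga_config(fitness = "product")
  ctx <- strain_context(m, cfg)
  expect_error(exhaustive_search(m, 2, cfg, context = ctx, budget = 3),
               "budget")
  base <- exhaustive_search(m, 0, cfg, context = ctx)
  expect_equal(base$n_evaluated, 1L)
  expect_equal(base$removed_reactions, character())
})

test_that("roulette selection also optimizes the fixture", {
  m <- toy_fixture("TOY-COUPLED")
  cfg <- ga_config(population_size = 20, max_generations = 40, rng_seed = 11,
                   fitness = "coupled", selection = "roulette")
  res <- run_ga(m, cfg)
  expect_equal(res$best$record$fitness, 0.25, tolerance = 1e-9)
})

test_that("thermodynamic weighting runs end to end in the GA", {
  m <- toy_fixture("TOY-COUPLED")
  # zero reaction energies give every mode dGp = 0: all feasible, weights
  # uniform, so the coupled optimum must match the equal-weighting one
  tt <- flat_thermo(m, 0)
  cfg <- ga_config(population_size = 20, max_generations = 40, rng_seed = 4,
                   fitness = "coupled", weighting_scheme = "thermodynamic")
  res <- run_ga(m, cfg, thermo = tt)
  expect_equal(res$best$record$fitness, 0.25, tolerance = 1e-9)

  # with energetically favoured product route, thermodynamic weighting
  # shifts flux towards it: product fraction at least the equal-weight one
  tt2 <- flat_thermo(m, -2)
  cfg2 <- ga_config(fitness = "product", weighting_scheme = "thermodynamic")
  ctx2 <- strain_context(m, cfg2, thermo = tt2)
  wt_t <- evaluate_strain(rep(1L, length(ctx2$deletable)), ctx2)
  ctx_e <- strain_context(m, ga_config(fitness = "product"))
  wt_e <- evaluate_strain(rep(1L, length(ctx_e$deletable)), ctx_e)
  expect_gte(wt_t$product_fraction, wt_e$product_fraction)
})
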