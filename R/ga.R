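#' Genetic algorithm configuration
#'
#' Defaults mirror common practice for small knockout-design problems:
#' a population of 50 with 5 elites, initial genotypes seeded with 2--6
#' random knockouts (seeding near the wild type keeps most of the initial
#' population viable), two-point crossover, uniform per-bit mutation, and
#' termination when the best fitness stalls (relative change below
#' `stall_tolerance` over `stall_generations` consecutive generations) or at
#' `max_generations`.
#'
#' @param population_size Individuals per generation.
#' @param elite_count Top individuals copied unchanged to the next
#'   generation (must be smaller than the population).
#' @param initial_knockouts_range Integer range of knockouts per seeded
#'   individual.
#' @param crossover_rate Probability a child is produced by two-point
#'   crossover rather than cloning.
#' @param mutation_rate Per-bit flip probability.
#' @param selection `"tournament"` (size 2) or `"roulette"`
#'   (fitness-proportional).
#' @param stall_tolerance Relative best-fitness change considered a stall.
#' @param stall_generations Consecutive stalled generations that trigger
#'   termination.
#' @param max_generations Hard generation cap.
#' @param rng_seed Integer seed for reproducibility (`NULL` = leave RNG
#'   state alone).
#' @param weighting_scheme `"equal"` or `"thermodynamic"` EM weighting for
#'   flux reconstruction.
#' @param fitness `"product"`, `"biomass"` or `"coupled"` (product of the
#'   two yield fractions).
#' @param temperature Kelvin, used by thermodynamic weighting.
#' @return A validated list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, elite_count = 5,
                      initial_knockouts_range = c(2L, 6L),
                      crossover_rate = 0.8, mutation_rate = 0.01,
                      selection = c("tournament", "roulette"),
                      stall_tolerance = 1e-6, stall_generations = 25,
                      max_generations = 100, rng_seed = NULL,
                      weighting_scheme = c("equal", "thermodynamic"),
                      fitness = c("coupled", "product", "biomass"),
                      temperature = 310.15) {
  selection <- match.arg(selection)
  weighting_scheme <- match.arg(weighting_scheme)
  fitness <- match.arg(fitness)
  stopifnot(
    population_size >= 2, elite_count >= 0, elite_count < population_size,
    length(initial_knockouts_range) == 2,
    initial_knockouts_range[1] >= 0,
    initial_knockouts_range[1] <= initial_knockouts_range[2],
    crossover_rate >= 0, crossover_rate <= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    stall_tolerance >= 0, max_generations >= 1, temperature > 0
  )
  structure(
    list(population_size = as.integer(population_size),
         elite_count = as.integer(elite_count),
         initial_knockouts_range = as.integer(initial_knockouts_range),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         selection = selection, stall_tolerance = stall_tolerance,
         stall_generations = as.integer(stall_generations),
         max_generations = as.integer(max_generations),
         rng_seed = rng_seed, weighting_scheme = weighting_scheme,
         fitness = fitness, temperature = temperature),
    class = "ga_config"
  )
}

#' Essential (protected) reactions of a model
#'
#' A reaction is essential when its single removal drives the maximal
#' product yield or the maximal biomass yield of the network to zero — any
#' strain lacking it makes either no product or no biomass. Essential
#' reactions are excluded from the knockout search and fixed to 1 in every
#' chromosome. Uses the knockout-subset property on the parent's modes, so
#' no re-enumeration is needed.
#'
#' @param model A [stoich_model()].
#' @param ems Parent `emset` (enumerated if not supplied).
#' @param tol Yield considered zero below this.
#' @return Character vector of protected reaction ids.
#' @export
essential_reactions <- function(model, ems = enumerate_efms(model),
                                tol = 1e-9) {
  protected <- character()
  for (r in model$reactions$id) {
    surv <- surviving_modes(ems, r)
    py <- max_yield(surv, model, "product")$value
    by <- max_yield(surv, model, "biomass")$value
    if (py <= tol || by <= tol) protected <- c(protected, r)
  }
  protected
}

#' Precomputed context for strain evaluation
#'
#' Enumerates the parent modes once, identifies the protected reaction set,
#' fixes the theoretical (parent) yields used as fitness denominators, and
#' precomputes pathway energies when thermodynamic weighting is requested.
#'
#' @param parent Parent [stoich_model()].
#' @param cfg A [ga_config()].
#' @param thermo A [thermo_table()] or `NULL` (required for thermodynamic
#'   weighting).
#' @param ems Optional pre-enumerated parent `emset`.
#' @return A list of class `strain_context`.
#' @export
strain_context <- function(parent, cfg = ga_config(), thermo = NULL,
                           ems = NULL) {
  if (cfg$weighting_scheme == "thermodynamic" && is.null(thermo)) {
    stop("thermodynamic weighting requires a thermo_table", call. = FALSE)
  }
  ems <- ems %||% enumerate_efms(parent)
  protected <- essential_reactions(parent, ems)
  yields <- mode_yields(ems, parent)
  theo_p <- max_yield(ems, parent, "product")$value
  theo_b <- max_yield(ems, parent, "biomass")$value
  dgp <- if (!is.null(thermo)) pathway_dG(ems, thermo) else NULL
  structure(
    list(parent = parent, cfg = cfg, ems = ems, protected = protected,
         deletable = setdiff(parent$reactions$id, protected),
         yields = yields, theoretical_product = theo_p,
         theoretical_biomass = theo_b, dgp = dgp),
    class = "strain_context"
  )
}

#' Evaluate a knockout strain
#'
#' Selects the parent modes whose supports avoid the removed reactions,
#' applies the configured EM weighting over the survivors, computes the
#' strain yields as the weight-averaged per-mode yields, and scales them by
#' the parent's theoretical yields to give the fitness fractions. Degenerate
#' strains (no surviving modes, or all survivors thermodynamically
#' infeasible) score 0 rather than erroring.
#'
#' @param chromosome Binary vector over the deletable reactions (1 = keep).
#' @param context A [strain_context()] (or a parent model, from which one is
#'   built — expensive if done repeatedly).
#' @param cfg,thermo Used only when `context` is a model.
#' @return A one-row fitness-record tibble: `product_fraction`,
#'   `biomass_fraction`, `coupled`, `fitness`, `n_modes`, `n_removals`.
#' @export
evaluate_strain <- function(chromosome, context, cfg = ga_config(),
                            thermo = NULL) {
  if (inherits(context, "stoich_model")) {
    context <- strain_context(context, cfg, thermo)
  }
  ctx <- context
  cfg <- ctx$cfg
  if (length(chromosome) != length(ctx$deletable)) {
    stop("chromosome length (", length(chromosome),
         ") does not match the number of deletable reactions (",
         length(ctx$deletable), ")", call. = FALSE)
  }
  removed <- ctx$deletable[chromosome == 0]
  keep <- !vapply(ctx$ems$supports, function(s) any(s %in% removed), TRUE)
  idx <- which(keep)
  rec <- function(pf, bf, nm) {
    pf <- min(1, max(0, pf)); bf <- min(1, max(0, bf))
    fit <- switch(cfg$fitness, product = pf, biomass = bf, coupled = pf * bf)
    tibble::tibble(product_fraction = pf, biomass_fraction = bf,
                   coupled = pf * bf, fitness = fit,
                   n_modes = nm, n_removals = length(removed))
  }
  if (length(idx) == 0L) return(rec(0, 0, 0L))

  if (cfg$weighting_scheme == "equal") {
    w <- rep(1 / length(idx), length(idx))
  } else {
    dgp <- ctx$dgp[idx]
    feasible <- dgp <= 0
    if (!any(feasible)) return(rec(0, 0, 0L))
    raw <- numeric(length(idx))
    expo <- -dgp[feasible] / (GAS_CONSTANT_KCAL * cfg$temperature)
    raw[feasible] <- exp(expo - max(expo))
    w <- raw / sum(raw)
  }
  py <- sum(w * ctx$yields$product_yield_mass[idx])
  by <- sum(w * ctx$yields$biomass_per_substrate[idx])
  pf <- if (ctx$theoretical_product > 0) py / ctx$theoretical_product else 0
  bf <- if (ctx$theoretical_biomass > 0) by / ctx$theoretical_biomass else 0
  rec(pf, bf, length(idx))
}

# Seed one chromosome with k knockouts, k uniform in the configured range.
seed_chromosome <- function(n_var, range) {
  k <- sample(seq(min(range[1], n_var), min(range[2], n_var)), 1)
  bits <- rep(1L, n_var)
  if (k > 0) bits[sample.int(n_var, k)] <- 0L
  bits
}

two_point_crossover <- function(a, b) {
  n <- length(a)
  if (n < 2) return(a)
  pts <- sort(sample.int(n - 1, min(2, n - 1)))
  child <- a
  if (length(pts) == 2) {
    child[(pts[1] + 1):pts[2]] <- b[(pts[1] + 1):pts[2]]
  } else {
    child[(pts[1] + 1):n] <- b[(pts[1] + 1):n]
  }
  child
}

select_parent <- function(fitness, method) {
  n <- length(fitness)
  if (method == "tournament") {
    cand <- sample.int(n, 2, replace = TRUE)
    cand[which.max(fitness[cand])]
  } else {
    tot <- sum(fitness)
    if (tot <= 0) sample.int(n, 1)
    else sample.int(n, 1, prob = fitness / tot)
  }
}

#' Run the single-objective knockout genetic algorithm
#'
#' Evolves a population of binary reaction-inclusion chromosomes over the
#' deletable (non-essential) reactions towards maximal fitness: product
#' yield fraction, biomass yield fraction, or their product ("coupled").
#' Strains are scored by [evaluate_strain()]; evaluations are cached by
#' genotype so repeated individuals cost nothing. Elites pass through
#' unchanged, so the best fitness is non-decreasing across generations.
#'
#' @param parent Parent [stoich_model()].
#' @param cfg A [ga_config()].
#' @param thermo A [thermo_table()] (needed for thermodynamic weighting).
#' @param context Optional precomputed [strain_context()].
#' @return A list of class `ga_result`: `best` (chromosome, fitness record,
#'   removed reactions, associated genes), `history` (tibble `generation`,
#'   `best_fitness`, `mean_fitness`), `n_evaluations`, `protected`, `cfg`.
#' @export
run_ga <- function(parent, cfg = ga_config(), thermo = NULL, context = NULL) {
  ctx <- context %||% strain_context(parent, cfg, thermo)
  ctx$cfg <- cfg
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  n_var <- length(ctx$deletable)
  if (n_var == 0L) stop("no deletable reactions to search", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(bits) {
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    rec <- evaluate_strain(bits, ctx)
    n_eval <<- n_eval + 1L
    cache[[key]] <- rec
    rec
  }

  pop <- lapply(seq_len(cfg$population_size), function(i) {
    seed_chromosome(n_var, cfg$initial_knockouts_range)
  })
  recs <- lapply(pop, score)
  fit <- vapply(recs, function(r) r$fitness, 0)

  history <- vector("list", cfg$max_generations)
  best_idx <- which.max(fit)
  best <- list(bits = pop[[best_idx]], record = recs[[best_idx]])
  stall <- 0L
  gens_run <- 0L

  for (gen in seq_len(cfg$max_generations)) {
    gens_run <- gen
    history[[gen]] <- tibble::tibble(generation = gen,
                                     best_fitness = best$record$fitness,
                                     mean_fitness = mean(fit))
    if (gen == cfg$max_generations) break
    prev_best <- best$record$fitness

    ord <- order(fit, decreasing = TRUE)
    elites <- pop[ord[seq_len(cfg$elite_count)]]
    children <- vector("list", cfg$population_size - cfg$elite_count)
    for (i in seq_along(children)) {
      p1 <- pop[[select_parent(fit, cfg$selection)]]
      p2 <- pop[[select_parent(fit, cfg$selection)]]
      child <- if (stats::runif(1) < cfg$crossover_rate) {
        two_point_crossover(p1, p2)
      } else p1
      flip <- stats::runif(n_var) < cfg$mutation_rate
      child[flip] <- 1L - child[flip]
      children[[i]] <- child
    }
    pop <- c(elites, children)
    recs <- lapply(pop, score)
    fit <- vapply(recs, function(r) r$fitness, 0)
    cand <- which.max(fit)
    if (fit[cand] > best$record$fitness) {
      best <- list(bits = pop[[cand]], record = recs[[cand]])
    }
    rel_change <- (best$record$fitness - prev_best) /
      max(abs(prev_best), .Machine$double.eps)
    stall <- if (rel_change < cfg$stall_tolerance) stall + 1L else 0L
    if (stall >= cfg$stall_generations) {
      history[[gen + 1L]] <- tibble::tibble(generation = gen + 1L,
                                            best_fitness = best$record$fitness,
                                            mean_fitness = mean(fit))
      gens_run <- gen + 1L
      break
    }
  }

  removed <- ctx$deletable[best$bits == 0]
  genes <- sort(unique(unlist(
    parent$reactions$genes[parent$reactions$id %in% removed]
  )))
  structure(
    list(best = list(chromosome = best$bits, record = best$record,
                     removed_reactions = removed, genes = genes),
         history = dplyr::bind_rows(history[seq_len(gens_run)]),
         n_evaluations = n_eval, protected = ctx$protected,
         deletable = ctx$deletable, cfg = cfg, model_name = parent$name),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> model ", x$model_name, ", fitness = ",
      format(x$best$record$fitness, digits = 4), " (", x$cfg$fitness, ", ",
      x$cfg$weighting_scheme, " weighting)\n", sep = "")
  cat("  ", nrow(x$history), " generations, ", x$n_evaluations,
      " strain evaluations, ", length(x$best$removed_reactions),
      " reactions removed\n", sep = "")
  invisible(x)
}

#' Exhaustive knockout search (oracle)
#'
#' Evaluates every knockout combination of the deletable reactions up to
#' `max_knockouts` removals and returns the best, with a deterministic
#' first-in-lexicographic-order tie-break (smaller knockout sets are
#' enumerated first). Refuses when the number of combinations exceeds the
#' budget; this is an oracle for validating [run_ga()] on toy models, not a
#' design tool.
#'
#' @param parent Parent [stoich_model()].
#' @param max_knockouts Maximum number of simultaneous removals.
#' @param cfg A [ga_config()] (fitness and weighting are honoured).
#' @param thermo Optional [thermo_table()].
#' @param context Optional precomputed [strain_context()].
#' @param budget Maximum number of combinations evaluated (default 1e6).
#' @return A list shaped like `ga_result$best` plus `n_evaluated`.
#' @export
exhaustive_search <- function(parent, max_knockouts, cfg = ga_config(),
                              thermo = NULL, context = NULL, budget = 1e6) {
  ctx <- context %||% strain_context(parent, cfg, thermo)
  ctx$cfg <- cfg
  n_var <- length(ctx$deletable)
  max_knockouts <- min(max_knockouts, n_var)
  total <- sum(choose(n_var, 0:max_knockouts))
  if (total > budget) {
    stop("exhaustive search would evaluate ", format(total, big.mark = ","),
         " combinations (budget ", format(budget, big.mark = ","), ")",
         call. = FALSE)
  }
  best_bits <- rep(1L, n_var)
  best_rec <- evaluate_strain(best_bits, ctx)
  n_evaluated <- 1L
  for (k in seq_len(max_knockouts)) {
    combs <- utils::combn(n_var, k)
    for (ci in seq_len(ncol(combs))) {
      bits <- rep(1L, n_var)
      bits[combs[, ci]] <- 0L
      rec <- evaluate_strain(bits, ctx)
      n_evaluated <- n_evaluated + 1L
      if (rec$fitness > best_rec$fitness + 1e-12) {
        best_rec <- rec; best_bits <- bits
      }
    }
  }
  removed <- ctx$deletable[best_bits == 0]
  genes <- sort(unique(unlist(
    parent$reactions$genes[parent$reactions$id %in% removed]
  )))
  list(chromosome = best_bits, record = best_rec,
       removed_reactions = removed, genes = genes, n_evaluated = n_evaluated)
}
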