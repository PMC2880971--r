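#' Pareto dominance filter
#'
#' Keeps the non-dominated points of a set of (maximized) objective pairs:
#' a point dominates another when it is at least as good on both objectives
#' and strictly better on at least one. Order-stable: survivors keep their
#' input order.
#'
#' @param points A data frame or matrix with two numeric columns (first and
#'   second objective).
#' @return Integer indices of the non-dominated points, in input order.
#' @export
dominance_filter <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n == 0L) return(integer())
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    dominated <- pts[, 1] >= pts[i, 1] & pts[, 2] >= pts[i, 2] &
      (pts[, 1] > pts[i, 1] | pts[, 2] > pts[i, 2])
    if (any(dominated)) keep[i] <- FALSE
  }
  which(keep)
}

# Fast non-dominated sorting: returns front rank (1 = non-dominated) per point.
nds_ranks <- function(pts) {
  n <- nrow(pts)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  r <- 1L
  while (length(remaining) > 0L) {
    idx <- remaining[dominance_filter(pts[remaining, , drop = FALSE])]
    rank[idx] <- r
    remaining <- setdiff(remaining, idx)
    r <- r + 1L
  }
  rank
}

# NSGA-II crowding distance within one front.
crowding_distance <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(rep(Inf, n))
  d <- rep(0, n)
  for (j in 1:2) {
    ord <- order(pts[, j])
    rng <- pts[ord[n], j] - pts[ord[1], j]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (pts[ord[i + 1], j] - pts[ord[i - 1], j]) / rng
      }
    }
  }
  d
}

# Hypervolume of a maximized 2-D front w.r.t. reference point (0, 0).
front_hypervolume <- function(pts) {
  if (nrow(pts) == 0L) return(0)
  keep <- dominance_filter(pts)
  pts <- pts[keep, , drop = FALSE]
  ord <- order(pts[, 1], decreasing = TRUE)
  pts <- pts[ord, , drop = FALSE]
  hv <- 0; prev_y <- 0
  for (i in seq_len(nrow(pts))) {
    hv <- hv + pts[i, 1] * max(0, pts[i, 2] - prev_y)
    prev_y <- max(prev_y, pts[i, 2])
  }
  hv
}

#' Run the multi-objective knockout genetic algorithm
#'
#' NSGA-II-style controlled-elitist search over knockout genotypes with two
#' maximized objectives: the product yield fraction and the biomass yield
#' fraction (both relative to the parent's theoretical yields). Survivors
#' are chosen by fast non-dominated sorting with crowding-distance
#' diversity; controlled elitism caps the fraction of the next generation
#' taken from the first front (`pareto_fraction`) so dominated-but-diverse
#' genotypes keep exploring. Terminates at `cfg$max_generations`.
#'
#' @param parent Parent [stoich_model()].
#' @param cfg A [ga_config()]; the conventional population size for the
#'   multi-objective search is 200 (pass
#'   `ga_config(population_size = 200, ...)`).
#' @param thermo Optional [thermo_table()].
#' @param context Optional precomputed [strain_context()].
#' @param pareto_fraction Cap on the fraction of the population carried from
#'   the first front (default 0.35).
#' @return A list of class `pareto_front`: `members` (tibble sorted by
#'   `product_fraction` descending: objectives, `n_removals`,
#'   `removed_reactions` list-column, `chromosome` list-column),
#'   `population` (tibble of the full final population's objectives),
#'   `front_fraction`, `hypervolume_history`, `cfg`.
#' @export
run_moga <- function(parent, cfg = ga_config(population_size = 200),
                     thermo = NULL, context = NULL, pareto_fraction = 0.35) {
  ctx <- context %||% strain_context(parent, cfg, thermo)
  ctx$cfg <- cfg
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  n_var <- length(ctx$deletable)
  if (n_var == 0L) stop("no deletable reactions to search", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  objectives <- function(bits) {
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    rec <- evaluate_strain(bits, ctx)
    out <- c(rec$product_fraction, rec$biomass_fraction)
    cache[[key]] <- out
    out
  }

  pop <- lapply(seq_len(cfg$population_size), function(i) {
    seed_chromosome(n_var, cfg$initial_knockouts_range)
  })
  obj <- t(vapply(pop, objectives, numeric(2)))
  hv_hist <- numeric(cfg$max_generations)

  for (gen in seq_len(cfg$max_generations)) {
    hv_hist[gen] <- front_hypervolume(obj)
    if (gen == cfg$max_generations) break

    ranks <- nds_ranks(obj)
    crowd <- rep(0, nrow(obj))
    for (r in unique(ranks)) {
      in_r <- which(ranks == r)
      crowd[in_r] <- crowding_distance(obj[in_r, , drop = FALSE])
    }
    pick <- function() {
      cand <- sample.int(length(pop), 2, replace = TRUE)
      a <- cand[1]; b <- cand[2]
      if (ranks[a] < ranks[b]) a
      else if (ranks[b] < ranks[a]) b
      else if (crowd[a] >= crowd[b]) a else b
    }
    children <- vector("list", cfg$population_size)
    for (i in seq_along(children)) {
      p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
      child <- if (stats::runif(1) < cfg$crossover_rate) {
        two_point_crossover(p1, p2)
      } else p1
      flip <- stats::runif(n_var) < cfg$mutation_rate
      child[flip] <- 1L - child[flip]
      children[[i]] <- child
    }
    child_obj <- t(vapply(children, objectives, numeric(2)))

    # controlled elitism over the combined pool: at most pareto_fraction of
    # the next population from the first front, rest filled rank by rank
    all_pop <- c(pop, children)
    all_obj <- rbind(obj, child_obj)
    all_rank <- nds_ranks(all_obj)
    all_crowd <- rep(0, nrow(all_obj))
    for (r in unique(all_rank)) {
      in_r <- which(all_rank == r)
      all_crowd[in_r] <- crowding_distance(all_obj[in_r, , drop = FALSE])
    }
    cap1 <- max(1L, ceiling(pareto_fraction * cfg$population_size))
    chosen <- integer()
    for (r in sort(unique(all_rank))) {
      in_r <- which(all_rank == r)
      in_r <- in_r[order(all_crowd[in_r], decreasing = TRUE)]
      room <- cfg$population_size - length(chosen)
      if (room <= 0L) break
      take <- if (r == 1L) min(length(in_r), cap1, room)
              else min(length(in_r), room)
      chosen <- c(chosen, in_r[seq_len(take)])
    }
    # if the first-front cap left the population short, top up by crowding
    if (length(chosen) < cfg$population_size) {
      left <- setdiff(order(all_rank, -all_crowd), chosen)
      chosen <- c(chosen,
                  left[seq_len(cfg$population_size - length(chosen))])
    }
    pop <- all_pop[chosen]
    obj <- all_obj[chosen, , drop = FALSE]
  }

  front_idx <- dominance_filter(obj)
  # deduplicate genotypes on the front
  keys <- vapply(pop[front_idx], paste, "", collapse = "")
  front_idx <- front_idx[!duplicated(keys)]
  removed <- lapply(pop[front_idx], function(b) ctx$deletable[b == 0])
  members <- tibble::tibble(
    product_fraction = obj[front_idx, 1],
    biomass_fraction = obj[front_idx, 2],
    n_removals = vapply(removed, length, 0L),
    removed_reactions = removed,
    chromosome = pop[front_idx]
  )
  members <- members[order(members$product_fraction,
                           decreasing = TRUE), , drop = FALSE]
  structure(
    list(members = members,
         population = tibble::tibble(product_fraction = obj[, 1],
                                     biomass_fraction = obj[, 2]),
         front_fraction = length(front_idx) / nrow(obj),
         hypervolume_history = hv_hist,
         protected = ctx$protected, cfg = cfg, model_name = parent$name),
    class = "pareto_front"
  )
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("<pareto_front> ", nrow(x$members), " non-inferior strains (model ",
      x$model_name, "; ", round(100 * x$front_fraction, 1),
      "% of final population on the front)\n", sep = "")
  best <- x$members[which.max(x$members$product_fraction *
                                x$members$biomass_fraction), ]
  cat("  best objective product: ",
      format(best$product_fraction * best$biomass_fraction, digits = 4),
      " (product ", format(best$product_fraction, digits = 4),
      ", biomass ", format(best$biomass_fraction, digits = 4), ")\n",
      sep = "")
  invisible(x)
}
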