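# Gas constant in kcal mol^-1 K^-1; all Gibbs energies in this package are
# standard-state values in kcal/mol.
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Assemble a thermodynamic table for a model
#'
#' Holds the standard Gibbs energy of reaction for every model reaction
#' (kcal/mol). Values may be supplied directly per reaction (`dGr`, which
#' takes precedence) or derived from per-metabolite standard Gibbs energies
#' of formation (`dGf`) and the full reaction stoichiometry — including
#' external/currency species, which do not constrain the steady-state
#' balance but must enter the energy bookkeeping.
#'
#' @param model A [stoich_model()].
#' @param dGf Named numeric vector, metabolite id -> Gibbs energy of
#'   formation (kcal/mol).
#' @param dGr Named numeric vector, reaction id -> Gibbs energy of reaction
#'   (kcal/mol); overrides values derived from `dGf`.
#' @return A `thermo_table`: list with `dGr` (named numeric, complete over
#'   model reactions) and the inputs.
#' @export
thermo_table <- function(model, dGf = NULL, dGr = NULL) {
  out <- stats::setNames(rep(NA_real_, nrow(model$reactions)),
                         model$reactions$id)
  if (!is.null(dGf)) {
    for (i in seq_len(nrow(model$reactions))) {
      out[i] <- reaction_dG(dGf, model$reactions$stoichiometry[[i]],
                            rxn_id = model$reactions$id[i])
    }
  }
  if (!is.null(dGr)) {
    hit <- intersect(names(dGr), names(out))
    out[hit] <- dGr[hit]
  }
  if (anyNA(out)) {
    stop("no Gibbs energy available for reaction(s): ",
         paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  }
  structure(list(dGr = out, dGf = dGf), class = "thermo_table")
}

#' Standard Gibbs energy of a reaction from formation energies
#'
#' `dGr = sum_i nu_i dGf_i` over the full stoichiometry (products positive,
#' substrates negative).
#'
#' @param dGf Named numeric vector of formation energies (kcal/mol).
#' @param stoich Named numeric vector of signed stoichiometric coefficients.
#' @param rxn_id Reaction id for error messages.
#' @return Gibbs energy of reaction, kcal/mol.
#' @export
reaction_dG <- function(dGf, stoich, rxn_id = "?") {
  missing_sp <- setdiff(names(stoich), names(dGf))
  if (length(missing_sp) > 0L) {
    stop("reaction '", rxn_id, "': no Gibbs energy of formation for ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  sum(stoich * dGf[names(stoich)])
}

#' Read Gibbs energy tables from CSV
#'
#' Formation energies: columns `metabolite,dGf_kcal_mol`. Reaction energies:
#' columns `reaction,dGr_kcal_mol`.
#'
#' @param path CSV path.
#' @return Named numeric vector (kcal/mol).
#' @export
read_dgf <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite", "dGf_kcal_mol") %in% names(tab))) {
    stop("formation energy CSV needs columns metabolite,dGf_kcal_mol",
         call. = FALSE)
  }
  stats::setNames(tab$dGf_kcal_mol, tab$metabolite)
}

#' @rdname read_dgf
#' @export
read_dgr <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("reaction", "dGr_kcal_mol") %in% names(tab))) {
    stop("reaction energy CSV needs columns reaction,dGr_kcal_mol",
         call. = FALSE)
  }
  stats::setNames(tab$dGr_kcal_mol, tab$reaction)
}

#' Pathway Gibbs energies of elementary modes
#'
#' The pathway energy of a mode is the coefficient-weighted sum of its
#' reaction energies, `dGp = sum_j e_j dGr_j`: a reversible reaction used
#' backwards (negative coefficient) contributes the negated reaction energy.
#' Modes are unit-substrate normalized, so pathway energies are per unit
#' substrate uptake and comparable across modes.
#'
#' @param ems An `emset`.
#' @param thermo A [thermo_table()].
#' @return Numeric vector, kcal/mol per mode.
#' @export
pathway_dG <- function(ems, thermo) {
  dgr <- thermo$dGr[ems$reaction_ids]
  if (anyNA(dgr)) {
    stop("thermo table is missing reaction(s): ",
         paste(ems$reaction_ids[is.na(dgr)], collapse = ", "), call. = FALSE)
  }
  as.numeric(crossprod(ems$M, dgr))
}

#' Count thermodynamically infeasible modes
#'
#' A mode is infeasible when its pathway standard Gibbs energy is positive.
#'
#' @param ems An `emset`.
#' @param thermo A [thermo_table()].
#' @return One-row tibble: `n_total`, `n_infeasible`, `fraction`,
#'   `mean_dGp`, `median_dGp`.
#' @export
feasibility_census <- function(ems, thermo) {
  dgp <- pathway_dG(ems, thermo)
  n <- length(dgp)
  tibble::tibble(
    n_total = n,
    n_infeasible = sum(dgp > 0),
    fraction = if (n > 0) sum(dgp > 0) / n else NA_real_,
    mean_dGp = if (n > 0) mean(dgp) else NA_real_,
    median_dGp = if (n > 0) stats::median(dgp) else NA_real_
  )
}

#' Equal EM weighting
#'
#' @param n Number of modes.
#' @return Numeric weight vector (`c_i = 1/n`, sum 1), with attribute
#'   `scheme = "equal"`. `n = 0` gives an empty vector.
#' @export
equal_weights <- function(n) {
  w <- if (n >= 1) rep(1 / n, n) else numeric()
  structure(w, scheme = "equal")
}

#' Thermodynamic (Boltzmann) EM weighting
#'
#' Feasible modes (`dGp <= 0`) receive raw weight `exp(-dGp / (R T))` with
#' `R = 1.9872e-3` kcal/mol/K; infeasible modes receive weight exactly 0.
#' Weights are normalized to sum 1. Exponents are shifted by their maximum
#' before exponentiation so large negative pathway energies cannot overflow
#' (the shift cancels in the normalization).
#'
#' @param ems An `emset`.
#' @param thermo A [thermo_table()].
#' @param temperature Temperature in kelvin (default 310.15, i.e. 37 C).
#' @return Numeric weight vector with attributes `scheme = "thermodynamic"`
#'   and `all_infeasible` (logical). If every mode is infeasible a zero
#'   vector is returned with a warning.
#' @export
thermo_weights <- function(ems, thermo, temperature = 310.15) {
  stopifnot(temperature > 0)
  dgp <- pathway_dG(ems, thermo)
  feasible <- dgp <= 0
  raw <- numeric(length(dgp))
  if (any(feasible)) {
    expo <- -dgp[feasible] / (GAS_CONSTANT_KCAL * temperature)
    raw[feasible] <- exp(expo - max(expo))
    w <- raw / sum(raw)
  } else {
    if (length(dgp) > 0) {
      warning("all modes are thermodynamically infeasible; zero weights",
              call. = FALSE)
    }
    w <- raw
  }
  structure(w, scheme = "thermodynamic", all_infeasible = !any(feasible))
}

#' Reconstruct a flux distribution from weighted elementary modes
#'
#' `v = M c`: the flux vector is the convex combination of the modes with
#' the given weights. Since every mode satisfies the steady-state balance,
#' so does any weighted combination.
#'
#' @param ems An `emset`.
#' @param weights Numeric weight vector, length [n_modes()].
#' @return A tibble with `reaction` and `flux` (per unit substrate uptake
#'   when the weighted modes consume substrate).
#' @export
reconstruct_flux <- function(ems, weights) {
  if (length(weights) != n_modes(ems)) {
    stop("weight vector length (", length(weights),
         ") does not match the number of modes (", n_modes(ems), ")",
         call. = FALSE)
  }
  v <- if (n_modes(ems) > 0) as.numeric(ems$M %*% weights)
       else rep(0, length(ems$reaction_ids))
  tibble::tibble(reaction = ems$reaction_ids, flux = v)
}

#' Strain yields under a weighting scheme
#'
#' The strain-level yields are the weight-averaged per-mode yields (modes
#' are unit-substrate normalized, so this equals the yields of the
#' reconstructed flux vector whenever all weighted modes consume substrate;
#' zero-substrate internal cycles carry weight but contribute zero yield).
#'
#' @param ems An `emset`.
#' @param model The source [stoich_model()].
#' @param weights Numeric weight vector over the modes.
#' @return One-row tibble: `product_yield_mass`, `biomass_per_substrate`.
#' @export
weighted_yields <- function(ems, model, weights) {
  if (n_modes(ems) == 0L || sum(weights) <= 0) {
    return(tibble::tibble(product_yield_mass = 0, biomass_per_substrate = 0))
  }
  ym <- mode_yields(ems, model)
  tibble::tibble(
    product_yield_mass = sum(weights * ym$product_yield_mass),
    biomass_per_substrate = sum(weights * ym$biomass_per_substrate)
  )
}
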