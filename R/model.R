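#' Build a stoichiometric model
#'
#' A `stoich_model` is the central container of the package: a set of
#' metabolites (internal metabolites are balanced at steady state, external
#' ones act as sources/sinks), a set of reactions with signed stoichiometric
#' coefficients and reversibility flags, and three designated reactions —
#' substrate uptake, product formation/excretion, and biomass synthesis —
#' that define the yields everything downstream is measured by.
#'
#' @param metabolites A data frame with columns `id`, `name` (optional) and
#'   `is_internal` (logical). Ids must be unique.
#' @param reactions A data frame with columns `id`, `reversible` (logical),
#'   `genes` (list-column of character vectors, optional) and `stoichiometry`
#'   (list-column of named numeric vectors: metabolite id -> signed
#'   coefficient, products positive).
#' @param substrate,product,biomass Reaction ids designating the substrate
#'   uptake, product formation and biomass reactions.
#' @param mw Named numeric vector of molecular weights (g/mol), at minimum
#'   for the substrate and product species used in mass-yield calculations.
#' @param name Optional model label.
#'
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(metabolites, reactions, substrate, product, biomass,
                         mw = numeric(), name = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"genes" %in% names(reactions)) {
    reactions$genes <- rep(list(character()), nrow(reactions))
  }

  if (nrow(reactions) == 0L) {
    stop("model has an empty reaction list", call. = FALSE)
  }
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(reactions))) {
    st <- reactions$stoichiometry[[i]]
    if (length(st) == 0L || all(st == 0)) {
      stop("reaction '", reactions$id[i], "' has no nonzero coefficient",
           call. = FALSE)
    }
    unknown <- setdiff(names(st), metabolites$id)
    if (length(unknown) > 0L) {
      stop("reaction '", reactions$id[i], "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  for (role in c(substrate = substrate, product = product, biomass = biomass)) {
    if (!role %in% reactions$id) {
      stop("designated reaction '", role, "' not found in the model",
           call. = FALSE)
    }
  }

  structure(
    list(
      name = name,
      metabolites = metabolites,
      reactions = reactions,
      substrate_rxn = substrate,
      product_rxn = product,
      biomass_rxn = biomass,
      mw = mw
    ),
    class = "stoich_model"
  )
}

#' @export
print.stoich_model <- function(x, ...) {
  n_int <- sum(x$metabolites$is_internal)
  cat("<stoich_model> ", x$name, "\n", sep = "")
  cat("  ", n_int, " internal metabolites (",
      nrow(x$metabolites) - n_int, " external), ",
      nrow(x$reactions), " reactions (",
      sum(x$reactions$reversible), " reversible)\n", sep = "")
  cat("  substrate: ", x$substrate_rxn,
      "  product: ", x$product_rxn,
      "  biomass: ", x$biomass_rxn, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Rows are metabolites, columns reactions. At steady state only internal
#' metabolites constrain the flux cone, so the default drops external rows;
#' the full matrix (used e.g. for Gibbs energy bookkeeping) is available with
#' `internal_only = FALSE`.
#'
#' @param model A [stoich_model()].
#' @param internal_only Keep only rows of internal metabolites (default).
#' @return A numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model, internal_only = TRUE) {
  mets <- model$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = nrow(model$reactions),
              dimnames = list(mets, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  if (internal_only) S <- S[model$metabolites$is_internal, , drop = FALSE]
  S
}

#' Reaction reversibility flags
#' @param model A [stoich_model()].
#' @return Named logical vector over reactions.
#' @export
reversibility <- function(model) {
  stats::setNames(model$reactions$reversible, model$reactions$id)
}

#' Apply reaction knockouts encoded by a binary chromosome
#'
#' The knockout genotype is a binary vector over the *deletable* reactions
#' (those not in `protected`): an entry of 1 keeps the reaction, 0 removes it.
#' Protected reactions — typically the essential set from
#' [essential_reactions()] — are always retained. The metabolite set is left
#' unchanged.
#'
#' @param model A [stoich_model()].
#' @param chromosome Binary (0/1) vector, one entry per deletable reaction in
#'   model order.
#' @param protected Character vector of always-kept reaction ids.
#' @return A [stoich_model()] containing the protected reactions plus those
#'   flagged 1.
#' @export
apply_knockouts <- function(model, chromosome, protected = character()) {
  deletable <- setdiff(model$reactions$id, protected)
  if (length(chromosome) != length(deletable)) {
    stop("chromosome length (", length(chromosome),
         ") does not match the number of deletable reactions (",
         length(deletable), ")", call. = FALSE)
  }
  keep_ids <- c(protected, deletable[chromosome == 1])
  keep <- model$reactions$id %in% keep_ids
  out <- model
  out$reactions <- model$reactions[keep, , drop = FALSE]
  out$name <- paste0(model$name, " [", sum(!keep), " knockouts]")
  # designated reactions may legitimately be knocked out in intermediate
  # strains; downstream yield code treats a missing column as zero flux
  out
}

#' Reaction ids removed by a chromosome
#' @param model A [stoich_model()].
#' @param chromosome Binary vector over deletable reactions.
#' @param protected Protected reaction ids.
#' @return Character vector of removed reaction ids.
#' @export
removed_reactions <- function(model, chromosome, protected = character()) {
  deletable <- setdiff(model$reactions$id, protected)
  deletable[chromosome == 0]
}
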