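#' Built-in toy fixture models
#'
#' Small networks whose complete elementary-mode sets are known analytically,
#' used throughout the test suite and as worked examples. All are verifiable
#' with [brute_force_efms()].
#'
#' * `TOY-BRANCH` — one internal metabolite `A`, three irreversible reactions
#'   (`UPT`: S_ext -> A; `PRD`: A -> P_ext; `BYP`: A -> B_ext). Exactly two
#'   elementary modes: \{UPT, PRD\} and \{UPT, BYP\}. `BYP` doubles as the
#'   biomass sink so all designations are populated.
#' * `TOY-REV` — linear chain with a reversible interconversion (`UPT`:
#'   S_ext -> A; `ISO`: A <-> B; `PRD`: B -> P_ext). Exactly one genuine mode
#'   \{UPT, ISO, PRD\}; the forward+backward 2-cycle of `ISO` is spurious and
#'   excluded.
#' * `TOY-COUPLED` — 8 reactions over internal `A`, `B` with distinct product
#'   and biomass routes, two waste sinks, a diversion reaction `LOW` that
#'   sends carbon to `P_ext` outside the designated product reaction (fluxes
#'   of the designated reactions alone count towards yields, so `LOW` is
#'   effectively waste), and an internal cycle. Elementary modes (6):
#'   \{UPT,ISO,PRD\} (product yield 1), \{UPT,ISO,BIO\} (biomass
#'   0.5/substrate), \{UPT,LOW\}, \{UPT,WA\}, \{UPT,ISO,WB\}, and the
#'   zero-substrate cycle \{ISO,CYC\}. Knocking out `WA` alone strictly
#'   improves the coupled product-x-biomass fitness (1/25 vs 1/36); the
#'   coupled optimum removes \{LOW, WA, WB, CYC\} for a fitness of 0.25.
#' * `TOY-ETHANOL` — glucose uptake, a lumped homoethanologenic route
#'   (GLC -> 2 ethanol + 2 CO2) with excretion reactions, and a biomass
#'   branch. Carries real molecular weights, so the maximal product mass
#'   yield is 2 x 46.069 / 180.156 = 0.511 g/g.
#'
#' @param name Fixture name, one of `"TOY-BRANCH"`, `"TOY-REV"`,
#'   `"TOY-COUPLED"`, `"TOY-ETHANOL"`.
#' @return A [stoich_model()].
#' @export
toy_fixture <- function(name = c("TOY-BRANCH", "TOY-REV", "TOY-COUPLED",
                                 "TOY-ETHANOL")) {
  name <- match.arg(name)
  rxn <- function(id, eq, rev = FALSE, genes = character()) {
    pe <- parse_reaction_equation(eq, id)
    list(id = id, reversible = rev || pe$reversible, genes = genes,
         stoich = pe$stoich)
  }
  build <- function(rows, substrate, product, biomass, mw = numeric()) {
    met_ids <- unique(unlist(lapply(rows, function(r) names(r$stoich))))
    stoich_model(
      metabolites = tibble::tibble(id = met_ids, name = met_ids,
                                   is_internal = !grepl("_ext$", met_ids)),
      reactions = tibble::tibble(
        id = vapply(rows, `[[`, "", "id"),
        reversible = vapply(rows, `[[`, TRUE, "reversible"),
        genes = lapply(rows, `[[`, "genes"),
        stoichiometry = lapply(rows, `[[`, "stoich")
      ),
      substrate = substrate, product = product, biomass = biomass,
      mw = mw, name = name
    )
  }

  switch(name,
    "TOY-BRANCH" = build(
      list(rxn("UPT", "S_ext -> A"),
           rxn("PRD", "A -> P_ext"),
           rxn("BYP", "A -> B_ext")),
      substrate = "UPT", product = "PRD", biomass = "BYP",
      mw = c(S_ext = 100, P_ext = 100)
    ),
    "TOY-REV" = build(
      list(rxn("UPT", "S_ext -> A"),
           rxn("ISO", "A <-> B"),
           rxn("PRD", "B -> P_ext")),
      substrate = "UPT", product = "PRD", biomass = "PRD",
      mw = c(S_ext = 100, P_ext = 100)
    ),
    "TOY-COUPLED" = build(
      list(rxn("UPT", "S_ext -> A", genes = "uptA"),
           rxn("ISO", "A <-> B", genes = "isoB"),
           rxn("PRD", "B -> P_ext", genes = "prdC"),
           rxn("LOW", "A -> 0.5 P_ext + 0.5 W_ext", genes = "lowD"),
           rxn("BIO", "A + B -> BM_ext", genes = "bioE"),
           rxn("WA", "A -> W_ext", genes = "wasF"),
           rxn("WB", "B -> W_ext", genes = "wasG"),
           rxn("CYC", "B -> A", genes = "cycH")),
      substrate = "UPT", product = "PRD", biomass = "BIO",
      mw = c(S_ext = 100, P_ext = 100)
    ),
    "TOY-ETHANOL" = build(
      list(rxn("UPT", "GLC_ext -> GLC", genes = "ptsG"),
           rxn("FEM", "GLC -> 2 ETH + 2 CO2", genes = c("pfk", "adhE")),
           rxn("EXE", "ETH -> ETH_ext"),
           rxn("EXC", "CO2 -> CO2_ext"),
           rxn("BIO", "GLC -> BM_ext", genes = "bio")),
      substrate = "UPT", product = "EXE", biomass = "BIO",
      mw = c(GLC_ext = 180.156, ETH_ext = 46.069)
    )
  )
}

#' Generate a random toy metabolic network
#'
#' Produces small random stoichiometric models used for property-based
#' testing of the enumeration code: a handful of internal metabolites, an
#' uptake and two excretion reactions, and random internal conversions (some
#' reversible). Each internal metabolite carries an implicit mass of
#' `2^(n_internal - i)` and conversion coefficients are chosen to conserve
#' that mass, so the networks cannot create product out of nothing — flux
#' through the product reaction always requires substrate uptake, as in a
#' real metabolic network. Networks are small enough for
#' [brute_force_efms()] to enumerate supports exhaustively.
#'
#' @param n_internal Number of internal metabolites (2--4).
#' @param n_reactions Total number of reactions (must allow the 3 fixed
#'   boundary reactions; capped at 12).
#' @param p_reversible Probability that an internal conversion is reversible.
#' @return A [stoich_model()].
#' @export
random_toy_model <- function(n_internal = 3, n_reactions = 8,
                             p_reversible = 0.25) {
  n_internal <- max(2L, min(4L, as.integer(n_internal)))
  n_reactions <- max(4L, min(12L, as.integer(n_reactions)))
  mets <- paste0("M", seq_len(n_internal))
  mass <- stats::setNames(2^(n_internal - seq_len(n_internal)), mets)
  rows <- list(
    list(id = "UPT", reversible = FALSE, genes = character(),
         stoich = c(S_ext = -1, stats::setNames(1, mets[1]))),
    list(id = "EXP", reversible = FALSE, genes = character(),
         stoich = c(stats::setNames(-1, mets[n_internal]), P_ext = 1)),
    list(id = "EXW", reversible = FALSE, genes = character(),
         stoich = c(stats::setNames(-1, sample(mets, 1)), W_ext = 1))
  )
  for (k in seq_len(n_reactions - 3L)) {
    from <- sample(mets, 1)
    to <- sample(setdiff(mets, from), 1)
    g <- min(mass[from], mass[to])
    rows[[length(rows) + 1L]] <- list(
      id = sprintf("R%02d", k),
      reversible = stats::runif(1) < p_reversible,
      genes = character(),
      stoich = c(stats::setNames(-unname(mass[to] / g), from),
                 stats::setNames(unname(mass[from] / g), to))
    )
  }
  met_ids <- unique(unlist(lapply(rows, function(r) names(r$stoich))))
  stoich_model(
    metabolites = tibble::tibble(id = met_ids, name = met_ids,
                                 is_internal = !grepl("_ext$", met_ids)),
    reactions = tibble::tibble(
      id = vapply(rows, `[[`, "", "id"),
      reversible = vapply(rows, `[[`, TRUE, "reversible"),
      genes = lapply(rows, `[[`, "genes"),
      stoichiometry = lapply(rows, `[[`, "stoich")
    ),
    substrate = "UPT", product = "EXP", biomass = "EXP",
    mw = c(S_ext = 100, P_ext = 100),
    name = "random-toy"
  )
}
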