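# Shared helpers for building tiny models in code.

support_strings <- function(ems) {
  vapply(mode_supports(ems), paste, "", collapse = "+")
}

# A model whose single irreversible reaction touches an internal metabolite:
# no steady state is possible, so the mode set is empty.
dead_end_model <- function() {
  stoich_model(
    metabolites = tibble::tibble(id = c("A", "S_ext"), name = c("A", "S"),
                                 is_internal = c(TRUE, FALSE)),
    reactions = tibble::tibble(
      id = "R1", reversible = FALSE, genes = list(character()),
      stoichiometry = list(c(S_ext = -1, A = 1))
    ),
    substrate = "R1", product = "R1", biomass = "R1",
    mw = c(S_ext = 100)
  )
}

# A linear substrate -> product chain: exactly one elementary mode.
single_route_model <- function() {
  stoich_model(
    metabolites = tibble::tibble(
      id = c("A", "S_ext", "P_ext"),
      is_internal = c(TRUE, FALSE, FALSE)
    ),
    reactions = tibble::tibble(
      id = c("UPT", "PRD"), reversible = c(FALSE, FALSE),
      genes = list(character(), character()),
      stoichiometry = list(c(S_ext = -1, A = 1), c(A = -1, P_ext = 1))
    ),
    substrate = "UPT", product = "PRD", biomass = "PRD",
    mw = c(S_ext = 100, P_ext = 100)
  )
}

# Uniform reaction Gibbs energy table for a model.
flat_thermo <- function(model, dgr = -2) {
  thermo_table(model, dGr = stats::setNames(rep(dgr, nrow(model$reactions)),
                                            model$reactions$id))
}
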