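test_that("reaction Gibbs energies are stoichiometric sums of formation energies", {
  expect_equal(reaction_dG(c(A = -10, B = -12), c(A = -1, B = 1)), -2)
  expect_equal(reaction_dG(c(A = -10), c(A = 0)), 0)  # A -> A nets to zero
  expect_equal(reaction_dG(c(A = -3, B = -5), c(A = -2, B = 1)), 1)
  expect_error(reaction_dG(c(A = -3), c(A = -1, B = 1), "RX"), "RX.*\\bB\\b")
})

test_that("thermo_table derives dGr from dGf and lets direct dGr override", {
  m <- single_route_model()
  tt <- thermo_table(m, dGf = c(S_ext = -5, A = -8, P_ext = -9))
  expect_equal(unname(tt$dGr), c(-3, -1))
  tt2 <- thermo_table(m, dGf = c(S_ext = -5, A = -8, P_ext = -9),
                      dGr = c(PRD = -7))
  expect_equal(unname(tt2$dGr), c(-3, -7))
  expect_error(thermo_table(m, dGf = c(S_ext = -5)), "no Gibbs energy")
})

test_that("pathway energies are coefficient-weighted reaction energy sums", {
  m <- single_route_model()
  e <- enumerate_efms(m)  # one mode, coefficients (1, 1)
  tt <- thermo_table(m, dGr = c(UPT = -5, PRD = -3))
  expect_equal(pathway_dG(e, tt), -8)

  # a mode using a reaction at coefficient 2 doubles its contribution
  m2 <- stoich_model(
    metabolites = tibble::tibble(id = c("A", "S_ext", "P_ext"),
                                 is_internal = c(TRUE, FALSE, FALSE)),
    reactions = tibble::tibble(
      id = c("UPT", "PRD"), reversible = FALSE,
      genes = list(character(), character()),
      stoichiometry = list(c(S_ext = -1, A = 2), c(A = -1, P_ext = 1))
    ),
    substrate = "UPT", product = "PRD", biomass = "PRD",
    mw = c(S_ext = 100, P_ext = 100)
  )
  e2 <- enumerate_efms(m2)  # (1, 2) per unit substrate
  tt2 <- thermo_table(m2, dGr = c(UPT = -5, PRD = 1))
  expect_equal(pathway_dG(e2, tt2), -3)
})

test_that("a reversible reaction used backwards contributes its negated energy", {
  m <- stoich_model(
    metabolites = tibble::tibble(id = c("A", "B", "S_ext", "P_ext"),
                                 is_internal = c(TRUE, TRUE, FALSE, FALSE)),
    reactions = tibble::tibble(
      id = c("UPT", "ISO", "PRD"), reversible = c(FALSE, TRUE, FALSE),
      genes = list(character(), character(), character()),
      # ISO is written B -> A, but the route needs A -> B (backward use)
      stoichiometry = list(c(S_ext = -1, A = 1), c(B = -1, A = 1),
                           c(B = -1, P_ext = 1))
    ),
    substrate = "UPT", product = "PRD", biomass = "PRD",
    mw = c(S_ext = 100, P_ext = 100)
  )
  e <- enumerate_efms(m)
  expect_equal(n_modes(e), 1L)
  expect_equal(unname(e$M["ISO", 1]), -1)  # backward use gives a signed coefficient
  tt <- thermo_table(m, dGr = c(UPT = -1, ISO = 4, PRD = -1))
  expect_equal(pathway_dG(e, tt), -6)
})

test_that("feasibility census counts positive pathway energies", {
  m <- toy_fixture("TOY-COUPLED")
  e <- enumerate_efms(m)
  expect_equal(feasibility_census(e, flat_thermo(m, -2))$n_infeasible, 0L)
  cs <- feasibility_census(e, flat_thermo(m, +2))
  expect_equal(cs$n_infeasible, n_modes(e))
  expect_equal(cs$fraction, 1)
})

test_that("equal weights are uniform and sum to one", {
  expect_equal(as.numeric(equal_weights(4)), rep(0.25, 4))
  expect_equal(as.numeric(equal_weights(1)), 1)
  expect_length(equal_weights(0), 0)
  for (n in c(3, 7, 101)) expect_equal(sum(equal_weights(n)), 1)
})

test_that("thermodynamic weights follow the Boltzmann closed form", {
  m <- toy_fixture("TOY-BRANCH")
  e <- enumerate_efms(m)  # two modes: UPT+PRD, UPT+BYP
  RT <- 1.9872e-3 * 310.15

  # energies differing by exactly RT ln 2 give weights (2/3, 1/3)
  tt <- thermo_table(m, dGr = c(UPT = 0, PRD = -RT * log(2), BYP = 0))
  w <- thermo_weights(e, tt)
  prd_mode <- which(support_strings(e) == "UPT+PRD")
  expect_equal(unname(w[prd_mode]), 2 / 3, tolerance = 1e-12)
  expect_equal(sum(w), 1)

  # one feasible, one infeasible: all weight on the feasible mode
  tt2 <- thermo_table(m, dGr = c(UPT = 0, PRD = -1, BYP = 5))
  w2 <- thermo_weights(e, tt2)
  expect_equal(unname(w2[prd_mode]), 1)
  expect_equal(unname(w2[-prd_mode]), 0)

  # single feasible mode carries weight one
  ms <- single_route_model()
  ws <- thermo_weights(enumerate_efms(ms), flat_thermo(ms, -1))
  expect_equal(as.numeric(ws), 1)

  # all infeasible: zero vector with a warning flag
  expect_warning(w0 <- thermo_weights(e, flat_thermo(m, +3)), "infeasible")
  expect_equal(as.numeric(w0), c(0, 0))
  expect_true(attr(w0, "all_infeasible"))
})

test_that("large negative pathway energies do not overflow the weighting", {
  m <- toy_fixture("TOY-BRANCH")
  e <- enumerate_efms(m)
  tt <- thermo_table(m, dGr = c(UPT = -500, PRD = -500, BYP = -499))
  w <- thermo_weights(e, tt)
  expect_true(all(is.finite(w)))
  expect_equal(sum(w), 1)
})

test_that("weights are monotone decreasing in pathway energy", {
  set.seed(33)
  m <- toy_fixture("TOY-COUPLED")
  e <- enumerate_efms(m)
  for (i in 1:10) {
    tt <- thermo_table(m, dGr = stats::setNames(stats::rnorm(8, -2, 3),
                                                m$reactions$id))
    dgp <- pathway_dG(e, tt)
    w <- suppressWarnings(thermo_weights(e, tt))
    ord <- order(dgp)
    expect_true(all(diff(w[ord]) <= 1e-12))
  }
})

test_that("thermodynamic weighting approaches equal weighting as T grows", {
  m <- toy_fixture("TOY-COUPLED")
  e <- enumerate_efms(m)
  tt <- flat_thermo(m, -2)  # all modes feasible
  w <- thermo_weights(e, tt, temperature = 1e9)
  expect_equal(as.numeric(w), as.numeric(equal_weights(n_modes(e))),
               tolerance = 1e-3)
})

test_that("flux reconstruction is the weighted mode combination", {
  m <- toy_fixture("TOY-BRANCH")
  e <- enumerate_efms(m)

  # unit weight on one mode returns that mode
  v <- reconstruct_flux(e, c(1, 0))
  expect_equal(v$flux, unname(e$M[, 1]))

  # equal weighting of the two branches: (1, 0.5, 0.5)
  v2 <- reconstruct_flux(e, equal_weights(2))
  expect_equal(stats::setNames(v2$flux, v2$reaction),
               c(UPT = 1, PRD = 0.5, BYP = 0.5))

  expect_error(reconstruct_flux(e, c(1, 0, 0)), "length")
})

test_that("any convex mode combination satisfies the steady-state balance", {
  set.seed(91)
  m <- toy_fixture("TOY-COUPLED")
  e <- enumerate_efms(m)
  S <- stoich_matrix(m)
  for (i in 1:10) {
    c_raw <- stats::runif(n_modes(e))
    v <- reconstruct_flux(e, c_raw / sum(c_raw))
    expect_lt(max(abs(S %*% v$flux)), 1e-9)
  }
})

test_that("Gibbs CSV readers validate their headers", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("metabolite,dGf_kcal_mol", "A,-10.5"), p)
  expect_equal(read_dgf(p), c(A = -10.5))
  writeLines(c("reaction,dGr_kcal_mol", "R1,2.5"), p)
  expect_equal(read_dgr(p), c(R1 = 2.5))
  writeLines(c("a,b", "x,1"), p)
  expect_error(read_dgf(p), "metabolite,dGf_kcal_mol")
  expect_error(read_dgr(p), "reaction,dGr_kcal_mol")
})
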