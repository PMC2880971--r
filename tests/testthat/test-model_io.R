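test_that("equation parser handles coefficients, reversibility and empty sides", {
  eq <- parse_reaction_equation("2 A + B -> C")
  expect_equal(eq$stoich, c(A = -2, B = -1, C = 1))
  expect_false(eq$reversible)

  eq <- parse_reaction_equation("A <-> B")
  expect_true(eq$reversible)
  expect_equal(eq$stoich, c(A = -1, B = 1))

  eq <- parse_reaction_equation("0.5 GLC + ATP -> 0.5 F16P")
  expect_equal(eq$stoich, c(GLC = -0.5, ATP = -1, F16P = 0.5))

  # one-sided equations: pure uptake / deliberately unbalanced product
  expect_equal(parse_reaction_equation("GLC_ext ->")$stoich, c(GLC_ext = -1))
  expect_equal(parse_reaction_equation("-> LYC")$stoich, c(LYC = 1))

  expect_error(parse_reaction_equation("A -+> B", "R9"), "R9")
})

test_that("model validation catches degenerate and inconsistent inputs", {
  mets <- tibble::tibble(id = c("A", "S_ext"), is_internal = c(TRUE, FALSE))
  rxn <- function(id, st) tibble::tibble(
    id = id, reversible = FALSE, genes = list(character()),
    stoichiometry = list(st)
  )
  expect_error(
    stoich_model(mets, rxn("R1", c(S_ext = -1, A = 1))[0, ], "R1", "R1", "R1"),
    "empty reaction list"
  )
  expect_error(
    stoich_model(mets, rxn("R1", c(S_ext = -1, B = 1)), "R1", "R1", "R1"),
    "R1.*unknown metabolite.*B"
  )
  expect_error(
    stoich_model(mets, rxn("R1", c(S_ext = -1, A = 1)), "R1", "R2", "R1"),
    "designated reaction 'R2'"
  )
  expect_error(
    stoich_model(mets, rxn("R1", c(A = 0)), "R1", "R1", "R1"),
    "no nonzero coefficient"
  )
})

test_that("TSV serialization round-trips models exactly", {
  for (fix in c("TOY-BRANCH", "TOY-REV", "TOY-COUPLED", "TOY-ETHANOL")) {
    m <- toy_fixture(fix)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_model(m, path)
    m2 <- read_model(path, mw = m$mw)
    expect_equal(stoich_matrix(m2), stoich_matrix(m), tolerance = 1e-12)
    expect_equal(stoich_matrix(m2, internal_only = FALSE),
                 stoich_matrix(m, internal_only = FALSE)[m2$metabolites$id, ],
                 tolerance = 1e-12)
    expect_equal(reversibility(m2), reversibility(m))
    expect_equal(m2$substrate_rxn, m$substrate_rxn)
    expect_equal(m2$product_rxn, m$product_rxn)
    expect_equal(m2$biomass_rxn, m$biomass_rxn)
    expect_equal(m2$reactions$genes, m$reactions$genes)
  }
})

test_that("external metabolites never enter the balanced matrix", {
  m <- toy_fixture("TOY-ETHANOL")
  S <- stoich_matrix(m)
  expect_false(any(grepl("_ext$", rownames(S))))
  S_full <- stoich_matrix(m, internal_only = FALSE)
  expect_true(all(grepl("_ext$", setdiff(rownames(S_full), rownames(S)))))
})

test_that("TSV loader reports missing designations and files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("R1\tS_ext -> A\t0\t", path)
  expect_error(read_model(path), "#substrate")
  expect_error(read_model(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("SBML reader recovers stoichiometry and reversibility", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="toy"><listOfSpecies>',
    '<species id="A" boundaryCondition="false"/>',
    '<species id="S_ext" boundaryCondition="true"/>',
    '<species id="P_ext" boundaryCondition="true"/>',
    "</listOfSpecies><listOfReactions>",
    '<reaction id="UPT" reversible="false">',
    '<listOfReactants><speciesReference species="S_ext" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    "</reaction>",
    '<reaction id="PRD" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="2"/></listOfReactants>',
    '<listOfProducts><speciesReference species="P_ext" stoichiometry="1"/></listOfProducts>',
    "</reaction>",
    "</listOfReactions></model></sbml>"
  )
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- read_model(path, format = "sbml", substrate = "UPT", product = "PRD",
                  biomass = "PRD")
  expect_equal(sort(m$metabolites$id), c("A", "P_ext", "S_ext"))
  expect_equal(unname(stoich_matrix(m)["A", ]), c(1, -2))
  expect_equal(unname(reversibility(m)), c(FALSE, TRUE))
})

test_that("molecular weight CSV reader validates its header", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,mw_g_per_mol", "GLC_ext,180.156"), path)
  expect_equal(read_mw(path), c(GLC_ext = 180.156))
  writeLines(c("name,weight", "x,1"), path)
  expect_error(read_mw(path), "species,mw_g_per_mol")
})

test_that("apply_knockouts keeps protected reactions and flagged ones only", {
  m <- toy_fixture("TOY-BRANCH")
  all_ones <- rep(1L, 3)
  expect_equal(apply_knockouts(m, all_ones)$reactions$id, m$reactions$id)

  protected <- "UPT"
  sub <- apply_knockouts(m, c(0L, 0L), protected)
  expect_equal(sub$reactions$id, "UPT")
  expect_equal(sub$metabolites, m$metabolites)

  expect_error(apply_knockouts(m, c(1L, 1L)), "chromosome length")
})

test_that("knocking out a branch removes exactly its modes", {
  m <- toy_fixture("TOY-BRANCH")
  sub <- apply_knockouts(m, c(1L, 1L, 0L))  # drop the byproduct branch
  expect_equal(nrow(sub$reactions), 2L)
  e_parent <- brute_force_efms(m)
  e_sub <- brute_force_efms(sub)
  expect_equal(n_modes(e_parent), 2L)
  expect_equal(n_modes(e_sub), 1L)
  expect_equal(support_strings(e_sub), "UPT+PRD")
})
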