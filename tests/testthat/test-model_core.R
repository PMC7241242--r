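test_that("bundled SBML fixture loads and round-trips", {
  path <- system.file("extdata", "toy_minimal.xml", package = "gemtailor")
  m <- read_gem(path)
  expect_equal(n_reactions(m), 4L)
  expect_equal(n_metabolites(m), 2L)
  expect_equal(objective_reaction(m), "BIO")

  out <- file.path(tempfile(fileext = ".xml"))
  write_gem(m, out)
  m2 <- read_gem(out)
  expect_true(models_equal(m, m2))
  # writer is deterministic: second write is byte-identical
  out2 <- tempfile(fileext = ".xml")
  write_gem(m2, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("round-trip preserves generated models, including edge content", {
  models <- list(
    generate_toy_gem(3, "standard"),
    random_toy(11), random_toy(12),
    # degenerate: zero-reaction model
    metabolic_model("empty",
                    data.frame(id = "A_c", name = "A", compartment = "c",
                               external_id = NA_character_),
                    data.frame(id = character(0), name = character(0),
                               reversible = logical(0),
                               lower_bound = numeric(0),
                               upper_bound = numeric(0),
                               subsystem = character(0),
                               gene_association = character(0),
                               objective_coefficient = numeric(0)),
                    stats::setNames(list(), character(0)),
                    c(c = "cytosol")))
  for (m in models) {
    f <- tempfile(fileext = ".xml")
    write_gem(m, f)
    expect_true(models_equal(m, read_gem(f)), label = m$id)
  }
})

test_that("reader handles Level 3 / fbc documents", {
  l3 <- c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">',
    '<model id="fbcToy" fbc:strict="true">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfParameters><parameter id="lb0" value="0" constant="true"/><parameter id="ub10" value="10" constant="true"/><parameter id="ubinf" value="INF" constant="true"/></listOfParameters>',
    '<listOfSpecies><species id="A_c" compartment="c"/><species id="B_c" compartment="c"/></listOfSpecies>',
    '<fbc:listOfGeneProducts><fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/><fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/></fbc:listOfGeneProducts>',
    '<fbc:listOfObjectives fbc:activeObjective="obj"><fbc:objective fbc:id="obj" fbc:type="maximize"><fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="BIO" fbc:coefficient="1"/></fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10"><listOfProducts><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfProducts></reaction>',
    '<reaction id="R1" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubinf"><notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: core</p></body></notes><listOfReactants><speciesReference species="A_c" stoichiometry="1" constant="true"/></listOfReactants><listOfProducts><speciesReference species="B_c" stoichiometry="1" constant="true"/></listOfProducts><fbc:geneProductAssociation><fbc:and><fbc:geneProductRef fbc:geneProduct="G_g1"/><fbc:geneProductRef fbc:geneProduct="G_g2"/></fbc:and></fbc:geneProductAssociation></reaction>',
    '<reaction id="BIO" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubinf"><listOfReactants><speciesReference species="B_c" stoichiometry="1" constant="true"/></listOfReactants></reaction>',
    '</listOfReactions></model></sbml>')
  f <- tempfile(fileext = ".xml")
  writeLines(l3, f)
  m <- read_gem(f)
  expect_equal(n_reactions(m), 3L)
  expect_equal(m$reactions$upper_bound,
               c(10, Inf, Inf))
  expect_equal(m$reactions$gene_association[2], "(g1 and g2)")
  expect_equal(m$reactions$subsystem[2], "core")
  expect_equal(objective_reaction(m), "BIO")
  # FBA agrees with the LP oracle on the parsed model
  orc <- brute_lp(m$reactions$objective_coefficient,
                  stoichiometric_matrix(m),
                  m$reactions$lower_bound, m$reactions$upper_bound)
  expect_equal(fba(m)$objective_value, orc$objval, tolerance = 1e-8)
})

test_that("malformed and inconsistent SBML produce informative errors", {
  bad <- tempfile(fileext = ".xml")
  writeLines("this is not xml <", bad)
  expect_error(read_gem(bad), "malformed SBML")

  f <- tempfile(fileext = ".xml")
  write_gem(toy1(), f)
  txt <- readLines(f)
  txt <- txt[!grepl('species id="B_c"', txt)]
  writeLines(txt, f)
  expect_error(read_gem(f), "R1.*undeclared species|undeclared species")
})

test_that("strip_constraints follows the reversibility rule and is idempotent", {
  m <- make_model("bounds", list(
    list(id = "IRR", sto = c(A = -1, B = 1), lb = 2, ub = 5),
    list(id = "REV", sto = c(A = -1, B = 1), rev = TRUE, lb = -3, ub = 3),
    list(id = "UP", sto = c(A = 1), ub = 10),
    list(id = "BIO", sto = c(B = -1), obj = 1)))
  s <- strip_constraints(m)
  expect_equal(s$reactions$lower_bound[s$reactions$id == "IRR"], 0)
  expect_equal(s$reactions$upper_bound[s$reactions$id == "IRR"], Inf)
  expect_equal(s$reactions$lower_bound[s$reactions$id == "REV"], -Inf)
  expect_equal(s$reactions$upper_bound[s$reactions$id == "REV"], Inf)
  # reversible <=> lower bound < 0 after stripping
  expect_equal(s$reactions$lower_bound < 0, s$reactions$reversible)
  # idempotent; original untouched; everything else preserved
  expect_true(models_equal(strip_constraints(s), s))
  expect_equal(m$reactions$lower_bound[1], 2)
  expect_identical(s$stoich, m$stoich)
  expect_identical(s$reactions$gene_association, m$reactions$gene_association)
  expect_identical(s$reactions$subsystem, m$reactions$subsystem)
})

test_that("stoichiometric matrix lays out signed coefficients exactly", {
  m <- toy1()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(n_metabolites(m), n_reactions(m)))
  expect_equal(S[, "R1"], c(A_c = -1, B_c = 1))
  expect_equal(S[, "EX_A"], c(A_c = 1, B_c = 0))  # single nonzero: exchange
  m2 <- make_model("coef", list(
    list(id = "R", sto = c(A = -2, B = 3)),
    list(id = "UP", sto = c(A = 1)),
    list(id = "OUT", sto = c(B = -1), obj = 1)))
  expect_equal(stoichiometric_matrix(m2)[, "R"], c(A = -2, B = 3))
})

test_that("model validation rejects broken inputs", {
  expect_error(make_model("dupid", list(
    list(id = "R1", sto = c(A = -1, B = 1)),
    list(id = "R1", sto = c(A = 1)))), "duplicate reaction ids")
  expect_error(make_model("badb", list(
    list(id = "R1", sto = c(A = -1, B = 1), lb = 5, ub = 2))),
    "lower_bound > upper_bound.*R1")
})

test_that("external id sidecar mapping attaches KEGG ids", {
  f <- tempfile(fileext = ".xml")
  write_gem(toy1(), f)
  map <- tempfile(fileext = ".tsv")
  writeLines("A_c\tC00031", map)
  m <- read_gem(f, external_id_map = map)
  expect_equal(m$metabolites$external_id[m$metabolites$id == "A_c"], "C00031")
  expect_true(is.na(m$metabolites$external_id[m$metabolites$id == "B_c"]))
})
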