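test_that("fba matches the basic-solution oracle on TOY1 and edge cases", {
  m <- toy1()
  s <- fba(m)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 10)
  orc <- brute_lp(m$reactions$objective_coefficient,
                  stoichiometric_matrix(m),
                  m$reactions$lower_bound, m$reactions$upper_bound)
  expect_equal(s$objective_value, orc$objval, tolerance = 1e-9)

  # all bounds zero -> Z = 0, still optimal
  z <- m
  z$reactions$lower_bound <- 0
  z$reactions$upper_bound <- 0
  sz <- fba(z)
  expect_equal(sz$status, "optimal")
  expect_equal(sz$objective_value, 0)

  # unproducible objective metabolite -> Z = 0
  u <- make_model("unprod", list(
    list(id = "UP", sto = c(A = 1), ub = 10),
    list(id = "SINK", sto = c(A = -1)),
    list(id = "BIO", sto = c(B = -1), obj = 1),
    list(id = "MK", sto = c(C = -1, B = 1))))   # B only from orphan C
  su <- fba(u)
  expect_equal(su$status, "optimal")
  expect_equal(su$objective_value, 0)
})

test_that("fba agrees with the oracle across generated toys and conserves mass", {
  for (seed in 1:8) {
    m <- random_toy(seed)
    s <- fba(m)
    orc <- brute_lp(m$reactions$objective_coefficient,
                    stoichiometric_matrix(m),
                    m$reactions$lower_bound, m$reactions$upper_bound)
    expect_equal(s$objective_value, orc$objval, tolerance = 1e-7,
                 label = m$id)
    # steady state: influx equals efflux for every metabolite
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% s$fluxes)), 1e-6)
    # sanity bound: objective cannot exceed uptake bound times best yield
    ub_up <- m$reactions$upper_bound[m$reactions$id == "UP"]
    expect_lte(s$objective_value, ub_up * 2^sum(grepl("^C", m$reactions$id)) + 1e-6)
  }
})

test_that("fba_min_norm picks the symmetric optimum and keeps Z", {
  m <- toy1()
  s <- fba_min_norm(m)
  expect_equal(s$fluxes[["R1"]], s$fluxes[["R2"]], tolerance = 1e-8)
  expect_equal(s$fluxes[["R1"]], 5, tolerance = 1e-4)
  expect_equal(s$objective_value, 10, tolerance = 1e-4 * 10)

  # norm is minimal among all optimal vertices (enumeration oracle)
  orc <- brute_lp(m$reactions$objective_coefficient,
                  stoichiometric_matrix(m),
                  m$reactions$lower_bound, m$reactions$upper_bound,
                  all_optima = TRUE)
  norms <- vapply(orc$optima, function(o) sum(o$v^2), numeric(1))
  expect_lte(sum(s$fluxes^2), min(norms) + 1e-6)

  # model with a unique optimum: min-norm fluxes equal plain FBA fluxes
  u <- make_model("uniq", list(
    list(id = "UP", sto = c(A = 1), ub = 4),
    list(id = "C1", sto = c(A = -1, B = 1)),
    list(id = "BIO", sto = c(B = -1), obj = 1)))
  expect_equal(fba_min_norm(u)$fluxes, fba(u)$fluxes, tolerance = 1e-4)
})

test_that("min-norm preserves the LP optimum on generated toys", {
  for (seed in 1:8) {
    m <- random_toy(seed + 100)
    z <- fba(m)$objective_value
    s <- fba_min_norm(m)
    expect_equal(s$objective_value, z, tolerance = 1e-4 * max(1, abs(z)),
                 label = m$id)
    S <- stoichiometric_matrix(m)
    expect_lt(max(abs(S %*% s$fluxes)), 1e-6)
  }
})

test_that("flux_sum implements the half-sum and its properties", {
  m <- toy1()
  s <- fba_min_norm(m)
  # A: influx 10, efflux 5 + 5 -> flux-sum 10
  expect_equal(flux_sum(s, m, "A_c")[["A_c"]], 10, tolerance = 1e-4)
  # steady state: flux-sum equals total influx for every metabolite
  S <- stoichiometric_matrix(m)
  influx <- rowSums(pmax(S * rep(s$fluxes, each = nrow(S)), 0))
  expect_equal(unname(flux_sum(s, m)), unname(influx), tolerance = 1e-6)
  # homogeneity: doubling fluxes doubles flux-sums
  s2 <- s
  s2$fluxes <- 2 * s$fluxes
  expect_equal(flux_sum(s2, m), 2 * flux_sum(s, m))
  # untouched metabolite -> 0
  z <- make_model("zero", list(
    list(id = "UP", sto = c(A = 1), ub = 1),
    list(id = "BIO", sto = c(A = -1), obj = 1),
    list(id = "DEAD", sto = c(D = 1), ub = 0)))
  expect_equal(flux_sum(fba(z), z, "D")[["D"]], 0)
  expect_error(flux_sum(s, m, "nope"), "unknown metabolite")
})

test_that("single-reaction deletion classifies TOY1 correctly", {
  m <- toy1()
  del <- single_reaction_deletion(m)
  expect_equal(nrow(del), 4L)
  get <- function(id, col) del[del$reaction_id == id, col]
  expect_equal(get("R1", "objective_after_deletion"), 10)   # R2 compensates
  expect_equal(get("R1", "essentiality_class"), "no_effect")
  expect_equal(get("EX_A", "objective_after_deletion"), 0)  # sole carbon
  expect_equal(get("EX_A", "essentiality_class"), "lethal")
  expect_equal(get("BIO", "essentiality_class"), "lethal")  # objective gone
  # invariant: deletion can never beat the wild type
  expect_true(all(del$objective_after_deletion <= 10 + 1e-6))
})

test_that("deleting a zero-flux reaction of a unique-optimum model is neutral", {
  u <- make_model("uniq2", list(
    list(id = "UP", sto = c(A = 1), ub = 4),
    list(id = "C1", sto = c(A = -1, B = 1)),
    list(id = "SIDE", sto = c(A = -1, C = 1)),   # dead end: zero flux
    list(id = "BIO", sto = c(B = -1), obj = 1)))
  s <- fba_min_norm(u)
  expect_equal(s$fluxes[["SIDE"]], 0)
  del <- single_reaction_deletion(u, "SIDE")
  expect_equal(del$objective_after_deletion, fba(u)$objective_value,
               tolerance = 1e-8)
})

test_that("reaction insertion grows the feasible set monotonically", {
  m <- toy1()
  # duplicate of an active pathway: no change
  r <- insert_reaction_and_evaluate(m, reaction("R3", c(A_c = -1, B_c = 1)))
  expect_equal(r$objective_before, r$objective_after)
  # disconnected reaction: no change
  r2 <- insert_reaction_and_evaluate(m, reaction("LONE", c(X_c = -1, Y_c = 1)))
  expect_equal(r2$objective_after, r2$objective_before)
  expect_true(all(c("X_c", "Y_c") %in% r2$model$metabolites$id))
  # widening a bottleneck raises the optimum
  b <- make_model("bneck", list(
    list(id = "UP", sto = c(A = 1), ub = 10),
    list(id = "C1", sto = c(A = -1, B = 1), ub = 3),
    list(id = "BIO", sto = c(B = -1), obj = 1)))
  r3 <- insert_reaction_and_evaluate(b, reaction("C2", c(A = -1, B = 1)))
  expect_equal(r3$objective_before, 3)
  expect_equal(r3$objective_after, 10)
  expect_gte(r3$objective_after, r3$objective_before - 1e-9)
  expect_error(insert_reaction_and_evaluate(m, reaction("R1", c(A_c = -1, B_c = 1))),
               "already present")
})

test_that("flux solutions export to TSV and JSON", {
  s <- fba(toy1())
  tsv <- tempfile(fileext = ".tsv")
  write_flux_solution(s, tsv)
  df <- read.delim(tsv)
  expect_equal(df$reaction_id, names(s$fluxes))
  expect_equal(df$flux, unname(s$fluxes))
  js <- tempfile(fileext = ".json")
  write_flux_solution(s, js, format = "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$objective_value, 10)
  expect_equal(parsed$status, "optimal")
})
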