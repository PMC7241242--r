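fake_solution <- function(fluxes) flux_solution(fluxes, 1, "optimal")

two_context_fixture <- function() {
  sols <- list(
    control_day1 = fake_solution(c(R1 = 2, R2 = 0.5, R3 = 0)),
    drought_day1 = fake_solution(c(R1 = 4, R2 = 0.5)))
  memb <- list(control_day1 = c("R1", "R2", "R3"),
               drought_day1 = c("R1", "R2"))
  build_flux_matrix(sols, memb)
}

test_that("flux matrix fill rule: one-tenth of the minimum positive entry", {
  fm <- two_context_fixture()
  expect_equal(fm$fill_value, 0.05)          # min positive 0.5 -> 0.05
  expect_equal(fm$values["drought_day1", "R3"], 0.05)   # absent: imputed
  expect_true(fm$fill_mask["drought_day1", "R3"])
  expect_equal(fm$values["control_day1", "R3"], 0.05)   # present zero: floored
  expect_true(fm$floor_mask["control_day1", "R3"])
  expect_false(fm$fill_mask["control_day1", "R1"])      # everywhere present
  expect_equal(sum(fm$fill_mask), 1L)
  # fill is strictly positive and <= every observed positive magnitude
  expect_gt(fm$fill_value, 0)
  expect_true(all(fm$values >= fm$fill_value - 1e-12))
  expect_error(build_flux_matrix(
    list(a_day1 = fake_solution(c(R1 = 0))), list(a_day1 = "R1")),
    "fill value undefined")
})

test_that("fold-change arithmetic, flags, and antisymmetry", {
  fm <- two_context_fixture()
  fc <- fold_change(fm, 1)
  get <- function(it, col) fc[fc$item == it, col]
  expect_equal(get("R1", "log2fc"), 1)          # 4 vs 2
  expect_true(get("R1", "flagged"))
  expect_equal(get("R2", "log2fc"), 0)          # equal
  expect_false(get("R2", "flagged"))
  expect_equal(get("R3", "log2fc"), 0)          # both filled at 0.05
  # imputed cell: ratio of the fill value (0.04) to the observed 0.4
  sols <- list(control_day1 = fake_solution(c(RA = 0.4, RB = 0.5)),
               drought_day1 = fake_solution(c(RB = 0.5)))
  memb <- list(control_day1 = c("RA", "RB"), drought_day1 = "RB")
  fm2 <- build_flux_matrix(sols, memb)
  fc2 <- fold_change(fm2, 1)
  expect_equal(fm2$fill_value, 0.04)
  expect_equal(fc2[fc2$item == "RA", "log2fc"], log2(0.04 / 0.4))
  expect_true(fc2[fc2$item == "RA", "flagged"])
  expect_true(fc2[fc2$item == "RA", "imputed_treatment"])
  # antisymmetry under condition swap
  swapped <- fold_change(fm, 1, conditions = c("control", "drought"))
  expect_equal(swapped$log2fc, -fc$log2fc)
  expect_error(fold_change(fm, 2), "absent from the matrix")
})

test_that("flux-sum matrix mirrors flux_sum and the fill rule", {
  m <- toy1()
  s <- fba_min_norm(m)
  sols <- list(control_day1 = s, drought_day1 = s)
  mods <- list(control_day1 = m, drought_day1 = m)
  fsm <- flux_sum_matrix(sols, mods)
  expect_equal(fsm$values["control_day1", "A_c"], 10, tolerance = 1e-4)
  expect_equal(sum(fsm$fill_mask), 0L)   # metabolite in every context
  # absent metabolite imputed at min positive / 10
  mB <- make_model("mini", list(
    list(id = "UP", sto = c(A = 1), ub = 2),
    list(id = "BIO", sto = c(A = -1), obj = 1)))
  sB <- fba(mB)
  fsm2 <- flux_sum_matrix(list(control_day1 = s, drought_day1 = sB),
                          list(control_day1 = m, drought_day1 = mB))
  expect_true(fsm2$fill_mask["drought_day1", "B_c"])
  pos <- c(fsm2$values[!fsm2$fill_mask & !fsm2$floor_mask])
  expect_equal(fsm2$fill_value, min(pos[pos > 0]) / 10)
})

test_that("flux-sum fold-change of a single-reaction metabolite tracks the flux", {
  # B is touched only by reaction R2 (and the drain); doubling R2's flux
  # doubles B's flux-sum, so both fold-changes match
  mk <- function(up) make_model(paste0("t", up), list(
    list(id = "UP", sto = c(A = 1), ub = up),
    list(id = "R2", sto = c(A = -1, B = 1)),
    list(id = "OUT", sto = c(B = -1), obj = 1)))
  mc <- mk(2); md <- mk(4)
  sc <- fba_min_norm(mc); sd <- fba_min_norm(md)
  fm <- build_flux_matrix(list(control_day1 = sc, drought_day1 = sd),
                          list(control_day1 = mc$reactions$id,
                               drought_day1 = md$reactions$id))
  fsm <- flux_sum_matrix(list(control_day1 = sc, drought_day1 = sd),
                         list(control_day1 = mc, drought_day1 = md))
  fc_flux <- fold_change(fm, 1)
  fc_fs <- fold_change(fsm, 1)
  expect_equal(fc_fs[fc_fs$item == "B", "log2fc"],
               fc_flux[fc_flux$item == "R2", "log2fc"], tolerance = 1e-6)
})

test_that("profile clustering matches the agglomeration oracle", {
  set.seed(26)
  base <- list(
    rising = function() cumsum(stats::runif(6, 0.5, 1)),
    falling = function() -cumsum(stats::runif(6, 0.5, 1)),
    humped = function() c(1, 3, 5, 5, 3, 1) + stats::rnorm(6, 0, 0.2))
  profs <- do.call(rbind, lapply(1:12, function(i) {
    base[[(i - 1) %% 3 + 1]]() + stats::rnorm(6, 0, 0.05)
  }))
  rownames(profs) <- sprintf("item%02d", 1:12)
  cl <- cluster_profiles(profs)
  orc <- brute_average_linkage(profs, height = 0.5)
  expect_identical(partition_signature(cl$cluster), partition_signature(orc))

  # invariance to item order
  perm <- sample(12)
  cl2 <- cluster_profiles(profs[perm, ])
  expect_identical(partition_signature(cl2$cluster),
                   partition_signature(cl$cluster))
})

test_that("clustering degenerate cases: identical, opposite, constant", {
  profs <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2,
                 c = c(4, 3, 2, 1), k = c(2, 2, 2, 2))
  cl <- cluster_profiles(profs)
  expect_equal(cl$cluster[["a"]], cl$cluster[["b"]])   # r = 1
  expect_false(cl$cluster[["a"]] == cl$cluster[["c"]]) # r = -1
  expect_true(cl$cluster[["k"]] != cl$cluster[["a"]])  # constant: singleton
  expect_equal(cl$constant, "k")
  # labels ordered by size then first id: {a,b} is cluster 1
  expect_equal(unname(cl$cluster[c("a", "b")]), c(1L, 1L))
})

test_that("occurrence percentage excludes metabolites missing globally", {
  global <- generate_toy_gem(3, "standard")
  # a context model missing some reported metabolites
  sub <- metabolic_model(
    "sub",
    global$metabolites[!global$metabolites$id %in% c("flv_c", "hpyr_x"), ],
    global$reactions[!global$reactions$id %in%
                       c("FLV1_c", "FLV2_c", "SGAT_x", "HPR_x"), ],
    global$stoich[!names(global$stoich) %in%
                    c("FLV1_c", "FLV2_c", "SGAT_x", "HPR_x")],
    global$compartments)
  reported <- c("g6p_c", "pyr_c", "glu_c", "flv_c", "hpyr_x", "ghost_met")
  # ghost_met is excluded from numerator and denominator: 3 of 5 remain
  expect_equal(occurrence_percentage(sub, reported, global), 60)
  expect_equal(occurrence_percentage(global, reported, global), 100)
  expect_error(occurrence_percentage(global, c("nope1", "nope2"), global),
               "no reported metabolite")
})

test_that("model census counts sizes, subsystems and condition-specific sets", {
  sc <- generate_scenario(seed = 5)
  res <- tailor_all(sc$gem, sc$expression$series, sc$growth, q_grid = 0.83)
  census <- model_census(res$gems)
  expect_equal(nrow(census$summary), 26L)
  for (g in res$gems) {
    expect_equal(census$summary$reactions[census$summary$context == g$context$key],
                 length(g$kept_reactions))
  }
  d13 <- census$condition_specific[["13"]]
  expect_setequal(d13$reactions$drought, sc$truths$drought_only_late)
  expect_setequal(d13$reactions$control, sc$truths$control_only_final)
  # flavonoid subsystem is richer in late drought models
  flav <- census$subsystems["flavonoid biosynthesis", ]
  expect_gt(flav[["drought_day13"]], flav[["control_day13"]])
  # identical models => no condition-specific members
  gid <- res$gems[["control_day1"]]
  gclone <- res$gems[["drought_day1"]]
  gclone$model <- gid$model
  census2 <- model_census(list(gid, gclone))
  expect_length(census2$condition_specific[["1"]]$reactions$control, 0)
  expect_length(census2$condition_specific[["1"]]$reactions$drought, 0)
})
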