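# Synthetic drought scenario.
#
# A compartmentalized toy plant GEM plus a 13-day x 2-condition expression
# and growth time course with planted ground truths, built so that every
# pipeline stage (threshold calibration, GIMME extraction, deletion and
# insertion screens, comparative analysis) can be exercised and checked
# against known answers without any external data.
#
# The stated world, in brief:
#  * Carbon enters as glucose (uptake bound 10), nitrogen as ammonium
#    (bound 5). Biomass drains one unit each of G6P, pyruvate and
#    glutamate, so the nitrogen-assimilation capacity caps growth.
#  * Three glutamate routes: GS1 (capacity 4.95, expressed except late
#    days), a stress-induced isoform GS2 (capacity 4.55, expressed only on
#    late days), and an uncapped GDH-like "key reaction" whose gene clears
#    the expression threshold only in late control contexts. Hence context
#    biomass optima: 4.95 early everywhere, 4.55 in late drought, 5.0
#    (nitrogen-limited) in late control - and deleting the key reaction
#    from the final-day control model reproduces the drought value, while
#    inserting it into the final-day drought model restores the control
#    value.
#  * Parallel cytosolic/plastidic glycolysis; the cytosolic branch is
#    transcriptionally shut down under late drought, shifting flux to the
#    capacity-limited plastid branch (large flux fold-changes).
#  * A flavonoid-like branch and a photorespiration-like peroxisomal loop
#    are induced late under drought: present in drought models but not
#    flux-carrying (model-content signal without a flux signal).
#  * Expression values fall into well-separated tiers (low 3.5, borderline
#    4.5-5.0, suppressed 6.2, active 9.0 on a log-like scale, replicate
#    noise sd 0.3). Tier cell counts are arranged so that the pooled
#    reaction-level distribution puts the active/inactive boundary exactly
#    at quantile 0.83: thresholds below it leave the late-day suppressed
#    genes active (no drought dip in simulated biomass), thresholds above
#    it only nibble at the active tier without changing any biomass value,
#    so 0.83 is the smallest quantile attaining the best growth match.

#' Parameters of the synthetic drought scenario
#'
#' One place for every stated constant of the generated world; tests and
#' documentation refer to these values.
#' @return named list of scenario constants.
#' @export
scenario_defaults <- function() {
  list(days = 13L, conditions = c("control", "drought"), replicates = 4L,
       sigma = 0.3,              # replicate noise sd, log-scale units
       tier_low = 3.5, tier_borderline = seq(4.5, 5.0, by = 0.1),
       tier_suppressed = 6.2, tier_active = 9.0,
       generative_quantile = 0.83,
       suppression_onset = 11L,  # first day the late-day programs switch
       flavonoid_onset = 9L,     # first drought day of flavonoid induction
       key_days = c(12L, 13L),   # control days with the key gene on
       divergence_day = 10L,     # last day drought growth tracks control
       growth_base = 0.5, growth_rate = 0.5,  # g, g/day (control)
       drought_rate_factor = 0.4,
       glc_uptake = 10, nh4_uptake = 5,
       gs1_cap = 4.95, gs2_cap = 4.55, plastid_cap = 10)
}

#' Generate a toy genome-scale model
#'
#' `size_class = "minimal"` builds the four-reaction network used
#' throughout the documentation (uptake bound 10, two parallel routes, a
#' biomass drain; FBA optimum 10). `"standard"` builds the ~50-reaction
#' compartmentalized drought scenario model described in
#' [scenario_defaults()], including transporters without gene
#' associations, parallel glycolysis in cytosol and plastid, a
#' three-precursor biomass drain and the uncapped "key" nitrogen
#' assimilation reaction.
#'
#' The network structure is fully deterministic; `seed` is recorded in the
#' model id for provenance only.
#'
#' @param seed integer seed (bookkeeping; the structure is deterministic).
#' @param size_class `"minimal"` or `"standard"`.
#' @return a `MetabolicModel`; for `"standard"`, with an `expr_program`
#'   attribute consumed by [generate_expression_series()].
#' @export
generate_toy_gem <- function(seed = 1L, size_class = c("standard", "minimal")) {
  size_class <- match.arg(size_class)
  if (size_class == "minimal") {
    mets <- data.frame(id = c("A_c", "B_c"), name = c("substrate", "precursor"),
                       compartment = "c", external_id = NA_character_,
                       stringsAsFactors = FALSE)
    rxns <- data.frame(
      id = c("EX_A", "R1", "R2", "BIO"),
      name = c("A uptake", "route 1", "route 2", "biomass drain"),
      reversible = FALSE, lower_bound = 0,
      upper_bound = c(10, Inf, Inf, Inf),
      subsystem = c("exchange", "core", "core", "biomass"),
      gene_association = "", objective_coefficient = c(0, 0, 0, 1),
      stringsAsFactors = FALSE)
    sto <- list(EX_A = c(A_c = 1), R1 = c(A_c = -1, B_c = 1),
                R2 = c(A_c = -1, B_c = 1), BIO = c(B_c = -1))
    return(metabolic_model(paste0("TOY1_seed", seed), mets, rxns, sto,
                           c(c = "cytosol")))
  }

  p <- scenario_defaults()
  comp <- c(e = "extracellular", c = "cytosol", p = "plastid",
            m = "mitochondrion", x = "peroxisome")
  met <- function(id, name, cmp, kegg = NA_character_) {
    data.frame(id = id, name = name, compartment = cmp, external_id = kegg,
               stringsAsFactors = FALSE)
  }
  mets <- rbind(
    met("glc_e", "glucose", "e", "C00031"),
    met("nh4_e", "ammonium", "e", "C01342"),
    met("glc_c", "glucose", "c", "C00031"),
    met("g6p_c", "glucose 6-phosphate", "c", "C00092"),
    met("pyr_c", "pyruvate", "c", "C00022"),
    met("nh4_c", "ammonium", "c", "C01342"),
    met("akg_c", "2-oxoglutarate", "c", "C00026"),
    met("glu_c", "glutamate", "c", "C00025"),
    met("g6p_p", "glucose 6-phosphate", "p", "C00092"),
    met("pyr_p", "pyruvate", "p", "C00022"),
    met("pyr_m", "pyruvate", "m", "C00022"),
    met("akg_m", "2-oxoglutarate", "m", "C00026"),
    met("ser_c", "serine", "c", "C00065"),
    met("ser_x", "serine", "x", "C00065"),
    met("hpyr_x", "hydroxypyruvate", "x", "C00168"),
    met("glyc_x", "glycerate", "x", "C00258"),
    met("glyc_c", "glycerate", "c", "C00258"),
    met("flv_c", "flavonoid precursor", "c"),
    met("flv2_c", "flavonoid", "c"))

  rxn_rows <- list()
  sto <- list()
  add <- function(id, name, sto_vec, subsystem, gpr = "", lb = 0, ub = Inf,
                  rev = FALSE, obj = 0) {
    rxn_rows[[id]] <<- data.frame(
      id = id, name = name, reversible = rev, lower_bound = lb,
      upper_bound = ub, subsystem = subsystem, gene_association = gpr,
      objective_coefficient = obj, stringsAsFactors = FALSE)
    sto[[id]] <<- sto_vec
  }

  add("EX_glc", "glucose supply", c(glc_e = 1), "exchange",
      ub = p$glc_uptake)
  add("EX_nh4", "ammonium supply", c(nh4_e = 1), "exchange",
      ub = p$nh4_uptake)
  add("T_glc", "glucose uptake transporter", c(glc_e = -1, glc_c = 1),
      "transport")
  add("T_nh4", "ammonium uptake transporter", c(nh4_e = -1, nh4_c = 1),
      "transport")
  add("T_g6p_p", "G6P plastid translocator", c(g6p_c = -1, g6p_p = 1),
      "transport", lb = -p$plastid_cap, ub = p$plastid_cap, rev = TRUE)
  add("T_pyr_p", "pyruvate plastid export", c(pyr_p = -1, pyr_c = 1),
      "transport")
  add("T_pyr_m", "pyruvate mitochondrial translocator",
      c(pyr_c = -1, pyr_m = 1), "transport")
  add("T_akg_m", "2-oxoglutarate export", c(akg_m = -1, akg_c = 1),
      "transport")
  add("T_ser_x", "serine peroxisomal translocator",
      c(ser_c = -1, ser_x = 1), "transport")
  add("T_glyc_x", "glycerate peroxisomal export",
      c(glyc_x = -1, glyc_c = 1), "transport")
  add("DM_flv", "flavonoid sink", c(flv2_c = -1), "demand")
  add("BIO", "biomass drain", c(g6p_c = -1, pyr_c = -1, glu_c = -1),
      "biomass", obj = 1)

  add("HXK_c", "hexokinase", c(glc_c = -1, g6p_c = 1),
      "glycolysis (cytosol)", gpr = "g_hxk")
  add("GLY_c", "glycolysis, cytosolic branch", c(g6p_c = -1, pyr_c = 2),
      "glycolysis (cytosol)", gpr = "g_glyc1 and g_glyc2")
  add("GLY_p", "glycolysis, plastidic branch", c(g6p_p = -1, pyr_p = 2),
      "glycolysis (plastid)", gpr = "g_glyp1 or g_glyp2")
  add("TCA_m", "pyruvate oxidation to 2-oxoglutarate",
      c(pyr_m = -1, akg_m = 1), "TCA cycle", gpr = "g_tca")
  add("GS1_c", "glutamate synthesis, constitutive",
      c(akg_c = -1, nh4_c = -1, glu_c = 1), "nitrogen assimilation",
      gpr = "g_gs1", ub = p$gs1_cap)
  add("GS2_c", "glutamate synthesis, stress-induced isoform",
      c(akg_c = -1, nh4_c = -1, glu_c = 1), "nitrogen assimilation",
      gpr = "g_gs2", ub = p$gs2_cap)
  add("GDH_c", "glutamate dehydrogenase analogue (key reaction)",
      c(akg_c = -1, nh4_c = -1, glu_c = 1), "nitrogen assimilation",
      gpr = "g_gdh")
  add("FLV1_c", "flavonoid branch, step 1", c(pyr_c = -1, flv_c = 1),
      "flavonoid biosynthesis", gpr = "g_flv1")
  add("FLV2_c", "flavonoid branch, step 2", c(flv_c = -1, flv2_c = 1),
      "flavonoid biosynthesis", gpr = "g_flv2")
  add("SER_c", "serine synthesis", c(pyr_c = -1, ser_c = 1),
      "photorespiration", gpr = "g_ser")
  add("SGAT_x", "serine-glyoxylate aminotransferase analogue",
      c(ser_x = -1, hpyr_x = 1), "photorespiration", gpr = "g_sgat")
  add("HPR_x", "hydroxypyruvate reductase analogue",
      c(hpyr_x = -1, glyc_x = 1), "photorespiration", gpr = "g_hpr")
  add("GLYK_c", "glycerate kinase analogue", c(glyc_c = -1, pyr_c = 1),
      "photorespiration", gpr = "g_glyk")

  # filler branches: dead-end drains that can never carry steady-state
  # flux; they give the expression pool its bulk
  filler_subsys <- c("purine metabolism", "pyrimidine metabolism",
                     "amino acid metabolism", "sugar metabolism")
  add("HSK_c", "housekeeping side branch", c(pyr_c = -1, hk1_c = 1),
      "amino acid metabolism", gpr = "g_hsk")
  for (i in 1:6) {
    add(sprintf("FB%d_c", i), sprintf("borderline side branch %d", i),
        stats::setNames(c(-1, 1), c("pyr_c", sprintf("fb%d_c", i))),
        filler_subsys[(i - 1) %% 4 + 1], gpr = sprintf("g_fb%d", i))
  }
  for (i in 1:20) {
    add(sprintf("FL%d_c", i), sprintf("low-expression side branch %d", i),
        stats::setNames(c(-1, 1), c("g6p_c", sprintf("fl%d_c", i))),
        filler_subsys[(i - 1) %% 4 + 1], gpr = sprintf("g_fl%d", i))
  }
  extra <- setdiff(unique(unlist(lapply(sto, names))), mets$id)
  mets <- rbind(mets, met(extra, extra, "c"))

  model <- metabolic_model(paste0("SynDrought_seed", seed),
                           mets, do.call(rbind, rxn_rows), sto, comp)
  attr(model, "expr_program") <- .expr_program(p)
  model
}

# Planted expression program: per gene, a baseline mean and optional
# (condition, day-window) overrides. Means refer to tiers in
# scenario_defaults(). Later rows override earlier ones.
.expr_program <- function(p = scenario_defaults()) {
  row <- function(gene, mean, condition = "both", from = 1L, to = p$days) {
    data.frame(gene = gene, mean = mean, condition = condition,
               from = from, to = to, stringsAsFactors = FALSE)
  }
  L <- p$tier_low; M <- p$tier_suppressed; H <- p$tier_active
  on <- p$suppression_onset
  prog <- rbind(
    row("g_hxk", H), row("g_tca", H), row("g_glyp1", H), row("g_glyp2", L),
    row("g_glyc1", H), row("g_glyc2", H),
    row("g_glyc1", L, "drought", on), row("g_glyc2", L, "drought", on),
    row("g_gs1", H), row("g_gs1", M, "both", on),
    row("g_gs2", L), row("g_gs2", H, "both", on),
    row("g_gdh", L),
    row("g_gdh", H, "control", p$key_days[1], p$key_days[length(p$key_days)]),
    row("g_flv1", L), row("g_flv1", H, "drought", p$flavonoid_onset),
    row("g_flv2", L), row("g_flv2", H, "drought", p$flavonoid_onset),
    row("g_ser", L), row("g_ser", H, "drought", on),
    row("g_sgat", L), row("g_sgat", H, "drought", on),
    row("g_hpr", L), row("g_hpr", H, "drought", on),
    row("g_glyk", L), row("g_glyk", H, "drought", on),
    row("g_hsk", H))
  for (i in 1:6) prog <- rbind(prog, row(sprintf("g_fb%d", i),
                                         p$tier_borderline[i]))
  for (i in 1:20) prog <- rbind(prog, row(sprintf("g_fl%d", i), L))
  prog
}

# Planted mean for one gene in one context.
.program_mean <- function(prog, gene, condition, day) {
  sel <- prog$gene == gene &
    (prog$condition == "both" | prog$condition == condition) &
    prog$from <= day & prog$to >= day
  if (!any(sel)) stop("no program entry for gene ", gene)
  prog$mean[max(which(sel))]
}

#' Generate the synthetic expression time course
#'
#' Per gene, condition, day and replicate: planted tier mean (the model's
#' `expr_program` attribute) plus Gaussian noise of sd `sigma` on the
#' log-like expression scale. Returns the raw gene-by-sample table, the
#' sample sheet, the replicate-averaged series and the noise-free planted
#' means.
#'
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param gem a `"standard"` [generate_toy_gem()] model (carries the
#'   expression program).
#' @param days number of days (default 13).
#' @param conditions condition labels.
#' @param replicates replicates per context (default 4).
#' @param sigma replicate noise standard deviation (default 0.3).
#' @return list with `table`, `sample_sheet`, `series`
#'   (an [expression_series()]) and `means` (planted, noise-free).
#' @export
generate_expression_series <- function(seed, gem, days = 13L,
                                       conditions = c("control", "drought"),
                                       replicates = 4L, sigma = 0.3) {
  prog <- attr(gem, "expr_program")
  if (is.null(prog)) stop("model carries no expression program ",
                          "(use generate_toy_gem(size_class = 'standard'))")
  if (replicates < 1) stop("need at least one replicate")
  genes <- model_genes(gem)
  ctx <- expand.grid(day = seq_len(days), condition = conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctx <- ctx[order(ctx$condition, ctx$day), c("condition", "day")]
  means <- matrix(NA_real_, nrow = length(genes), ncol = nrow(ctx),
                  dimnames = list(genes,
                                  context_key(ctx$condition, ctx$day)))
  for (k in seq_len(nrow(ctx))) {
    means[, k] <- vapply(genes, .program_mean, numeric(1), prog = prog,
                         condition = ctx$condition[k], day = ctx$day[k])
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed) + 1L)

  sample_sheet <- do.call(rbind, lapply(seq_len(nrow(ctx)), function(k) {
    data.frame(sample_id = sprintf("%s_r%d",
                                   context_key(ctx$condition[k], ctx$day[k]),
                                   seq_len(replicates)),
               condition = ctx$condition[k], day = ctx$day[k],
               replicate = seq_len(replicates), stringsAsFactors = FALSE)
  }))
  tab <- matrix(NA_real_, nrow = length(genes), ncol = nrow(sample_sheet),
                dimnames = list(genes, sample_sheet$sample_id))
  for (s in seq_len(nrow(sample_sheet))) {
    key <- context_key(sample_sheet$condition[s], sample_sheet$day[s])
    tab[, s] <- means[, key] + stats::rnorm(length(genes), 0, sigma)
  }
  series <- average_replicates(tab, sample_sheet)
  list(table = tab, sample_sheet = sample_sheet, series = series,
       means = means)
}

#' Generate the synthetic growth series
#'
#' Control rosette fresh weight grows at a constant rate; drought tracks
#' control through the divergence day, after which its growth rate falls
#' by the stated factor. The series is deterministic (`seed` recorded for
#' provenance).
#'
#' @param seed integer seed (bookkeeping).
#' @param days number of days.
#' @param base fresh weight on day 1 (g).
#' @param rate control growth rate (g/day).
#' @param divergence_day last day drought tracks control.
#' @param drop_factor multiplier on the drought growth rate afterwards.
#' @return data.frame: `condition`, `day`, `fresh_weight_g`.
#' @export
generate_growth_series <- function(seed = 1L, days = 13L, base = 0.5,
                                   rate = 0.5, divergence_day = 10L,
                                   drop_factor = 0.4) {
  d <- seq_len(days)
  control <- base + rate * (d - 1)
  inc <- ifelse(d <= divergence_day, rate, rate * drop_factor)
  drought <- base + cumsum(c(0, inc[-1]))
  rbind(data.frame(condition = "control", day = d, fresh_weight_g = control,
                   stringsAsFactors = FALSE),
        data.frame(condition = "drought", day = d, fresh_weight_g = drought,
                   stringsAsFactors = FALSE))
}

#' Generate the full synthetic drought scenario
#'
#' Bundles the standard toy model, expression time course, growth series
#' and the planted ground truths into one object; regeneration from the
#' same seed is bit-identical.
#'
#' @param seed master integer seed; per-generator streams are derived from
#'   it.
#' @param sigma replicate noise sd (0 gives noise-free planted values).
#' @return object of class `SyntheticScenario` with elements `gem`,
#'   `expression` (list from [generate_expression_series()]), `growth`,
#'   `params`, and `truths` (planted facts: key reaction and gene, the
#'   generative quantile, divergence day, per-context planted active
#'   reactions, late-day condition-specific reaction sets).
#' @export
generate_scenario <- function(seed = 1L, sigma = scenario_defaults()$sigma) {
  p <- scenario_defaults()
  gem <- generate_toy_gem(seed, "standard")
  expr <- generate_expression_series(seed, gem, days = p$days,
                                     conditions = p$conditions,
                                     replicates = p$replicates,
                                     sigma = sigma)
  growth <- generate_growth_series(seed, days = p$days,
                                   base = p$growth_base,
                                   rate = p$growth_rate,
                                   divergence_day = p$divergence_day,
                                   drop_factor = p$drought_rate_factor)

  # planted active (above-threshold) mapped reactions per context
  prog <- attr(gem, "expr_program")
  ctx <- expr$series$contexts
  mapped <- gem$reactions$id[nzchar(gem$reactions$gene_association)]
  cutoff <- (p$tier_suppressed + p$tier_active) / 2   # inside the tier gap
  active <- matrix(FALSE, nrow = length(mapped), ncol = nrow(ctx),
                   dimnames = list(mapped, ctx$key))
  for (k in seq_len(nrow(ctx))) {
    gv <- stats::setNames(
      vapply(model_genes(gem), .program_mean, numeric(1), prog = prog,
             condition = ctx$condition[k], day = ctx$day[k]),
      model_genes(gem))
    rx <- map_expression_to_reactions(gem, gv)
    active[, k] <- rx[mapped] >= cutoff
  }

  truths <- list(
    key_reaction = "GDH_c", key_gene = "g_gdh",
    key_contexts = context_key("control", p$key_days),
    generative_quantile = p$generative_quantile,
    divergence_day = p$divergence_day,
    suppressed_reactions = c("GLY_c", "GS1_c"),
    induced_reactions = c("GS2_c", "FLV1_c", "FLV2_c", "SER_c", "SGAT_x",
                          "HPR_x", "GLYK_c"),
    drought_only_late = c("FLV1_c", "FLV2_c", "SER_c", "SGAT_x", "HPR_x",
                          "GLYK_c"),
    control_only_final = c("GLY_c", "GDH_c"),
    planted_active = active)
  structure(list(gem = gem, expression = expr, growth = growth,
                 params = p, seed = as.integer(seed), truths = truths),
            class = "SyntheticScenario")
}

#' Write a scenario to disk in pipeline input formats
#'
#' Emits the SBML model, expression TSV, sample sheet TSV, growth TSV, a
#' reported-metabolites list and `truths.json` into a directory; these are
#' exactly the files [run_pipeline()] consumes.
#'
#' @param scenario a [generate_scenario()] object.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gem = file.path(dir, "model.xml"),
    expression = file.path(dir, "expression.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    growth = file.path(dir, "growth.tsv"),
    reported = file.path(dir, "reported_metabolites.txt"),
    truths = file.path(dir, "truths.json"))
  write_gem(scenario$gem, paths[["gem"]])
  tab <- data.frame(gene = rownames(scenario$expression$table),
                    scenario$expression$table, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scenario$expression$sample_sheet,
                     paths[["sample_sheet"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scenario$growth, paths[["growth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # a plausible "measured metabolites" panel: core intermediates plus two
  # ids absent from the model (exercising the exclusion rule)
  reported <- c("g6p_c", "pyr_c", "glu_c", "akg_c", "ser_c", "glyc_c",
                "flv_c", "hpyr_x", "not_in_model_1", "not_in_model_2")
  writeLines(reported, paths[["reported"]])
  tr <- scenario$truths
  tr$planted_active <- NULL                    # matrices stay in R
  tr$seed <- scenario$seed
  jsonlite::write_json(tr, paths[["truths"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
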