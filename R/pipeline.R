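# End-to-end pipeline driver: config handling, stage orchestration,
# artifact writing, and the final-day deletion/insertion screen.

.config_error <- function(...) {
  stop(structure(class = c("gemtailor_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.infeasible_error <- function(...) {
  stop(structure(class = c("gemtailor_infeasible_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Assemble and validate a pipeline configuration
#'
#' @param paths named list of input paths: `gem`, `expression`,
#'   `sample_sheet`, `growth`, and optionally `reported_metabolites` and
#'   `external_id_map`.
#' @param q_grid threshold quantile grid (default 0.70-0.90 step 0.01).
#' @param objective_fraction GIMME biomass floor fraction (default 0.9).
#' @param zero_tol flux zero tolerance.
#' @param fold_change_factor flag threshold on the ratio scale (default 2).
#' @param cluster_cut correlation cut for profile clustering (default 0.5).
#' @param strip_constraints strip preset bounds from the global model
#'   before tailoring (default `TRUE`; the synthetic scenario sets `FALSE`
#'   because its bounds encode the nutrient medium).
#' @param seed integer seed recorded in the manifest.
#' @return validated config list of class `PipelineConfig`.
#' @export
pipeline_config <- function(paths, q_grid = seq(0.70, 0.90, by = 0.01),
                            objective_fraction = 0.9,
                            zero_tol = GEM_ZERO_TOL,
                            fold_change_factor = 2, cluster_cut = 0.5,
                            strip_constraints = TRUE, seed = 1L) {
  required <- c("gem", "expression", "sample_sheet", "growth")
  missing_keys <- setdiff(required, names(paths))
  if (length(missing_keys)) {
    .config_error("config lacks input path(s): ",
                  paste(missing_keys, collapse = ", "))
  }
  for (key in intersect(names(paths), c(required, "reported_metabolites",
                                        "external_id_map"))) {
    if (!file.exists(paths[[key]])) {
      .config_error("input file not found (", key, "): ", paths[[key]])
    }
  }
  if (!length(q_grid) || any(q_grid < 0 | q_grid > 1)) {
    .config_error("quantile grid must lie within [0, 1]")
  }
  if (objective_fraction <= 0 || objective_fraction > 1) {
    .config_error("objective_fraction must be in (0, 1]")
  }
  if (fold_change_factor <= 1) {
    .config_error("fold_change_factor must exceed 1")
  }
  structure(list(paths = paths, q_grid = q_grid,
                 objective_fraction = objective_fraction,
                 zero_tol = zero_tol,
                 fold_change_factor = fold_change_factor,
                 cluster_cut = cluster_cut,
                 strip_constraints = isTRUE(strip_constraints),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with the fields of [pipeline_config()].
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .config_error("config file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) .config_error("unreadable config: ",
                                                    conditionMessage(e)))
  base <- dirname(normalizePath(path))
  paths <- lapply(raw$paths, function(p) {
    if (is.character(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base, p)
    else p
  })
  args <- raw[setdiff(names(raw), "paths")]
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, c(list(paths = paths),
                             args[intersect(names(args), known)]))
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes, in order: model loading (and optional constraint stripping),
#' replicate averaging, GIMME tailoring across the quantile grid with
#' growth-trajectory calibration, per-context norm-regularized FBA, the
#' final-day deletion/insertion screen, flux and flux-sum fold-change
#' tables, correlation clustering, census and occurrence summaries, and a
#' manifest with config and checksums. Artifacts are plain TSV/JSON/SBML
#' files under `out_dir`.
#'
#' @param config a `PipelineConfig` (or path to a JSON config).
#' @param out_dir output directory (created; existing files overwritten).
#' @return invisibly, a list with the in-memory stage results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[gemtailor] ", ...)

  # -- stage 1: global model ----------------------------------------------
  log_msg("loading model: ", config$paths$gem)
  global <- read_gem(config$paths$gem,
                     external_id_map = config$paths$external_id_map)
  if (config$strip_constraints) {
    global <- strip_constraints(global)
    log_msg("stripped preset constraints")
  }
  write_gem(global, file.path(out_dir, "global_model.xml"))
  gfba <- fba(global)
  if (gfba$status != "optimal" || gfba$objective_value <= 0) {
    .infeasible_error("global model FBA is ", gfba$status,
                      " (objective ", format(gfba$objective_value), ")")
  }
  log_msg("global optimum: ", format(gfba$objective_value))

  # -- stage 2: expression and growth -------------------------------------
  tab <- utils::read.delim(config$paths$expression, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- tab[[1L]]
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- genes
  sheet <- utils::read.delim(config$paths$sample_sheet,
                             stringsAsFactors = FALSE)
  series <- average_replicates(mat, sheet)
  growth <- utils::read.delim(config$paths$growth, stringsAsFactors = FALSE)
  log_msg("expression: ", nrow(mat), " genes, ",
          nrow(series$contexts), " contexts")

  # -- stage 3: tailoring sweep -------------------------------------------
  tl <- tailor_all(global, series, growth, q_grid = config$q_grid,
                   objective_fraction = config$objective_fraction,
                   zero_tol = config$zero_tol)
  gems <- tl$gems
  report <- tl$report
  log_msg("selected quantile: ", report$selected_quantile)
  gem_dir <- file.path(out_dir, "context_gems")
  dir.create(gem_dir, showWarnings = FALSE)
  for (g in gems) {
    write_gem(g$model, file.path(gem_dir, paste0(g$context$key, ".xml")))
  }
  .write_tsv(report$per_quantile, file.path(out_dir, "quantile_sweep.tsv"),
             comment = "per-quantile tailoring scores; similarity = Pearson r of simulated biomass vs observed fresh-weight rate")
  jsonlite::write_json(
    list(selected_quantile = report$selected_quantile,
         selected_threshold = report$selected_threshold,
         objective_fraction = report$objective_fraction,
         parent_objective = report$parent_objective,
         pool = report$pool, similarity = report$similarity,
         quantile_convention = "sorted-array linear interpolation (R type 7)",
         regularization = "two-stage: LP optimum, then QP min ||v||^2 at 1e-6 relative give-back"),
    file.path(out_dir, "tailoring_report.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)

  # -- stage 4: per-context regularized FBA -------------------------------
  solutions <- lapply(gems, function(g) fba_min_norm(g$model))
  flux_long <- do.call(rbind, lapply(names(solutions), function(k) {
    data.frame(context = k, reaction_id = names(solutions[[k]]$fluxes),
               flux = unname(solutions[[k]]$fluxes),
               stringsAsFactors = FALSE)
  }))
  .write_tsv(flux_long, file.path(out_dir, "fluxes.tsv"),
             comment = "norm-regularized FBA fluxes per context model (mmol/gDW/h convention)")
  biomass <- data.frame(
    context = names(gems),
    biomass = vapply(gems, function(g) g$biomass_rate, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  .write_tsv(biomass, file.path(out_dir, "biomass_rates.tsv"),
             comment = "context-model FBA biomass optima (model units)")

  # -- stage 5: final-day deletion/insertion screen -----------------------
  days <- vapply(gems, function(g) g$context$day, integer(1))
  conds <- vapply(gems, function(g) g$context$condition, character(1))
  final_day <- max(days)
  screen <- NULL
  cond2 <- sort(unique(conds))
  if (length(cond2) == 2) {
    kc <- context_key(cond2[1], final_day)
    kd <- context_key(cond2[2], final_day)
    if (all(c(kc, kd) %in% names(gems))) {
      screen <- screen_final_day(gems[[kc]], gems[[kd]])
      .write_tsv(screen$deletions, file.path(out_dir, "deletion_screen.tsv"),
                 comment = paste0("single-reaction deletion on ", kc,
                                  "; candidates match the ", kd,
                                  " biomass within tolerance"))
      .write_tsv(screen$candidates, file.path(out_dir, "insertion_screen.tsv"),
                 comment = paste0("candidate reactions inserted into ", kd))
    }
  }

  # -- stage 6: comparative analysis --------------------------------------
  memberships <- lapply(gems, function(g) g$model$reactions$id)
  fm <- build_flux_matrix(solutions, memberships)
  fsm <- flux_sum_matrix(solutions, gems)
  both_days <- sort(unique(days))
  comparative <- list()
  for (what in c("flux", "flux_sum")) {
    mx <- if (what == "flux") fm else fsm
    profs <- fold_change_profiles(mx, both_days,
                                  conditions = rev(cond2),
                                  factor = config$fold_change_factor)
    long <- do.call(rbind, lapply(both_days, function(d) {
      fc <- fold_change(mx, d, conditions = rev(cond2),
                        factor = config$fold_change_factor)
      cbind(day = d, fc)
    }))
    .write_tsv(long, file.path(out_dir, paste0(what, "_fold_change.tsv")),
               comment = paste0("log2(", cond2[2], "/", cond2[1],
                                ") of ", what,
                                " magnitudes; fill value = ",
                                format(mx$fill_value)))
    cl <- NULL
    if (nrow(profs$filtered) >= 2) {
      cl <- cluster_profiles(profs$filtered, cut = config$cluster_cut)
      .write_tsv(data.frame(item = names(cl$cluster),
                            cluster = unname(cl$cluster)),
                 file.path(out_dir, paste0(what, "_clusters.tsv")),
                 comment = paste0("average-linkage clustering, distance 1 - Pearson r, cut ",
                                  1 - config$cluster_cut))
    }
    comparative[[what]] <- list(matrix = mx, profiles = profs, clusters = cl)
  }

  # -- stage 7: census and occurrence -------------------------------------
  census <- model_census(gems)
  .write_tsv(census$summary, file.path(out_dir, "census.tsv"),
             comment = "context model sizes")
  .write_tsv(data.frame(subsystem = rownames(census$subsystems),
                        census$subsystems, check.names = FALSE),
             file.path(out_dir, "census_subsystems.tsv"),
             comment = "reactions per subsystem per context model")
  occurrence <- NULL
  if (!is.null(config$paths$reported_metabolites)) {
    reported <- readLines(config$paths$reported_metabolites)
    reported <- reported[nzchar(trimws(reported))]
    occurrence <- data.frame(
      context = names(gems),
      occurrence_pct = vapply(gems, occurrence_percentage, numeric(1),
                              reported = reported, global = global),
      row.names = NULL, stringsAsFactors = FALSE)
    .write_tsv(occurrence, file.path(out_dir, "occurrence.tsv"),
               comment = "percentage of reported metabolites present per context model (after global-model exclusion)")
  }

  # -- manifest ------------------------------------------------------------
  artifacts <- list.files(out_dir, recursive = TRUE)
  artifacts <- setdiff(artifacts, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, artifacts))
  manifest <- list(
    package = "gemtailor",
    version = as.character(utils::packageVersion("gemtailor")),
    seed = config$seed,
    config = list(q_grid = config$q_grid,
                  objective_fraction = config$objective_fraction,
                  zero_tol = config$zero_tol,
                  fold_change_factor = config$fold_change_factor,
                  cluster_cut = config$cluster_cut,
                  strip_constraints = config$strip_constraints,
                  paths = config$paths),
    artifacts = stats::setNames(as.list(unname(sums)), artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("wrote ", length(artifacts) + 1L, " artifacts to ", out_dir)

  invisible(list(global = global, gems = gems, report = report,
                 solutions = solutions, screen = screen,
                 comparative = comparative, census = census,
                 occurrence = occurrence, out_dir = out_dir))
}

# Rebuild a Reaction object from a model's reaction table row.
.reaction_from_model <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  rx <- model$reactions[i, ]
  reaction(id = rx$id, stoichiometry = model$stoich[[id]], name = rx$name,
           reversible = rx$reversible, lower_bound = rx$lower_bound,
           upper_bound = rx$upper_bound, subsystem = rx$subsystem,
           gene_association = rx$gene_association,
           objective_coefficient = rx$objective_coefficient)
}

#' Final-day deletion/insertion screen
#'
#' Runs a single-reaction deletion screen on the control context model;
#' reactions whose deletion brings the control biomass to the drought
#' model's biomass (within relative tolerance) are selected and inserted
#' one by one into the drought model, recording the biomass before and
#' after each insertion. If the two models already have equal biomass the
#' screen is degenerate (every no-effect deletion would "match") and is
#' reported as such, with no candidates.
#'
#' @param control_gem,drought_gem `ContextGEM` (or `MetabolicModel`)
#'   objects for the same day.
#' @param tol relative tolerance for "same biomass" (default `1e-6`).
#' @return list of class `ScreenReport`: `control_biomass`,
#'   `drought_biomass`, `degenerate`, `deletions` (full screen table),
#'   `candidates` (data.frame: reaction_id, objective_before,
#'   objective_after).
#' @export
screen_final_day <- function(control_gem, drought_gem, tol = 1e-6) {
  cm <- if (inherits(control_gem, "ContextGEM")) control_gem$model else control_gem
  dm <- if (inherits(drought_gem, "ContextGEM")) drought_gem$model else drought_gem
  zc <- fba(cm)$objective_value
  zd <- fba(dm)$objective_value
  scale <- max(abs(zc), 1)
  degenerate <- abs(zc - zd) <= tol * scale
  deletions <- single_reaction_deletion(cm, tol = tol)
  if (degenerate) {
    return(structure(list(control_biomass = zc, drought_biomass = zd,
                          degenerate = TRUE, deletions = deletions,
                          candidates = data.frame(
                            reaction_id = character(0),
                            objective_before = numeric(0),
                            objective_after = numeric(0))),
                     class = "ScreenReport"))
  }
  sel <- deletions$reaction_id[
    abs(deletions$objective_after_deletion - zd) <= tol * scale]
  cand <- do.call(rbind, lapply(sel, function(id) {
    res <- insert_reaction_and_evaluate(dm, .reaction_from_model(cm, id),
                                        replace = id %in% dm$reactions$id)
    data.frame(reaction_id = id,
               objective_before = res$objective_before,
               objective_after = res$objective_after,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) {
    cand <- data.frame(reaction_id = character(0),
                       objective_before = numeric(0),
                       objective_after = numeric(0))
  }
  structure(list(control_biomass = zc, drought_biomass = zd,
                 degenerate = FALSE, deletions = deletions,
                 candidates = cand),
            class = "ScreenReport")
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat("ScreenReport: control biomass ", format(x$control_biomass),
      ", drought biomass ", format(x$drought_biomass),
      if (x$degenerate) " (degenerate: equal biomass)", "\n", sep = "")
  if (nrow(x$candidates)) {
    cat("candidates:\n")
    print(x$candidates)
  } else cat("no candidate reactions\n")
  invisible(x)
}
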