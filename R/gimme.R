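# GIMME context-specific model extraction.
#
# Given reaction-level expression for one (condition, day) context and a
# global threshold, GIMME penalizes flux through below-threshold reactions
# (weight = threshold - expression) while requiring the biomass objective
# to stay at or above a fraction (default 90%) of the parent model's
# optimum. Reactions with zero weight (expressed above threshold, or with
# no gene association) are always kept; below-threshold reactions are kept
# only if the penalty LP still routes flux through them ("reinserted"),
# otherwise they are removed from the context model.

#' GIMME penalty weights
#'
#' `weight = max(0, threshold - expression)` per reaction; reactions with
#' absent expression (no gene association, or no usable measurement) get
#' weight 0 and are therefore never penalized.
#'
#' @param rxn_expr named numeric vector of reaction-level expression
#'   (NA = absent), as produced by [map_expression_to_reactions()].
#' @param threshold expression threshold (same units as `rxn_expr`).
#' @param quantile optional bookkeeping: the quantile `threshold` was
#'   derived from.
#' @return object of class `GimmeWeights`.
#' @export
gimme_weights <- function(rxn_expr, threshold, quantile = NA_real_) {
  stopifnot(is.finite(threshold))
  w <- pmax(0, threshold - rxn_expr)
  names(w) <- names(rxn_expr)
  w[is.na(w)] <- 0
  structure(list(weights = w, threshold = threshold, quantile = quantile),
            class = "GimmeWeights")
}

#' GIMME penalty linear program
#'
#' Minimizes `sum(w * |v|)` subject to steady state, the model bounds, and
#' `biomass >= objective_fraction * Z*` where `Z*` is the parent model's
#' FBA optimum. Absolute values are realized by splitting reversible
#' reactions into non-negative forward/backward parts carrying the same
#' weight.
#'
#' @param model a `MetabolicModel`.
#' @param weights a [gimme_weights()] object (aligned with the model's
#'   reactions).
#' @param objective_fraction fraction of the parent optimum the context
#'   model must retain (default 0.9).
#' @param parent_objective optionally, a precomputed parent optimum `Z*`.
#' @return list of class `GimmeSolution`: `fluxes` (net, per reaction),
#'   `penalty` (objective of the minimization), `biomass`, `status`.
#' @export
gimme_lp <- function(model, weights, objective_fraction = 0.9,
                     parent_objective = NULL) {
  stopifnot(inherits(weights, "GimmeWeights"))
  w <- weights$weights[model$reactions$id]
  if (anyNA(w)) stop("weights do not cover every reaction")
  if (is.null(parent_objective)) {
    parent <- fba(model)
    if (parent$status != "optimal") {
      stop("parent model FBA is ", parent$status)
    }
    parent_objective <- parent$objective_value
  }
  if (parent_objective <= 0) {
    stop("parent optimum must be positive for GIMME (got ",
         format(parent_objective), ")")
  }
  zmin <- objective_fraction * parent_objective

  S <- stoichiometric_matrix(model)
  lb <- pmax(model$reactions$lower_bound, -GEM_BIG)
  ub <- pmin(model$reactions$upper_bound, GEM_BIG)
  obj <- model$reactions$objective_coefficient
  n <- length(w)
  rev_idx <- which(lb < 0)

  # variables: forward part per reaction, backward part per reversible
  # reaction, then one surplus for the biomass floor
  nb <- length(rev_idx)
  lo <- c(pmax(lb, 0), rep(0, nb), 0)
  hi <- c(ub, -lb[rev_idx], GEM_BIG)
  cost <- c(w, w[rev_idx], 0)
  Anet <- cbind(S, -S[, rev_idx, drop = FALSE], 0)
  biom <- c(obj, -obj[rev_idx], -1)
  Aeq <- rbind(Anet, biom)
  beq <- c(rep(0, nrow(S)), zmin)

  res <- lp_solve(cost, Aeq, beq, lo, hi, sense = "min")
  if (res$status != "optimal") {
    stop("GIMME LP ", res$status, " at objective fraction ",
         objective_fraction)
  }
  v <- res$x[seq_len(n)]
  v[rev_idx] <- v[rev_idx] - res$x[n + seq_len(nb)]
  v[abs(v) < GEM_ZERO_TOL] <- 0
  structure(list(fluxes = stats::setNames(v, model$reactions$id),
                 penalty = res$objval, biomass = sum(obj * v),
                 status = res$status),
            class = "GimmeSolution")
}

#' Extract a context-specific model from a GIMME solution
#'
#' Keeps every zero-weight reaction (above threshold or without
#' expression) plus the below-threshold reactions that still carry flux in
#' the penalty solution (recorded as reinserted); removes the rest and
#' prunes metabolites no remaining reaction touches. The resulting
#' sub-model is verified to attain at least `objective_fraction` of the
#' parent optimum.
#'
#' @param model the parent `MetabolicModel`.
#' @param weights the [gimme_weights()] used.
#' @param gimme_solution the matching [gimme_lp()] solution.
#' @param context list with `condition` and `day` (see [context_key()]).
#' @param objective_fraction fraction of the parent optimum (default 0.9).
#' @param parent_objective precomputed parent optimum `Z*` (computed if
#'   missing).
#' @param zero_tol |flux| above this counts as carrying flux.
#' @return object of class `ContextGEM`.
#' @export
extract_context_gem <- function(model, weights, gimme_solution, context,
                                objective_fraction = 0.9,
                                parent_objective = NULL,
                                zero_tol = GEM_ZERO_TOL) {
  stopifnot(inherits(weights, "GimmeWeights"),
            inherits(gimme_solution, "GimmeSolution"))
  ids <- model$reactions$id
  w <- weights$weights[ids]
  v <- gimme_solution$fluxes[ids]
  active <- abs(v) > zero_tol
  keep <- w == 0 | active
  reinserted <- ids[w > 0 & active]
  removed <- ids[!keep]

  sub <- .remove_reactions(model, removed, prune = TRUE)
  sub$id <- paste0(model$id, "_", context_key(context$condition, context$day))
  if (is.null(parent_objective)) parent_objective <- fba(model)$objective_value
  chk <- fba(sub)
  if (chk$status != "optimal" ||
      chk$objective_value < objective_fraction * parent_objective - 1e-6) {
    stop("internal consistency error: context model misses the ",
         objective_fraction, " objective floor (check zero tolerance)")
  }
  structure(list(model = sub,
                 context = list(condition = context$condition,
                                day = as.integer(context$day),
                                key = context_key(context$condition,
                                                  context$day)),
                 kept_reactions = ids[keep],
                 removed_reactions = removed,
                 reinserted_reactions = reinserted,
                 gimme_objective = gimme_solution$penalty,
                 biomass_rate = chk$objective_value,
                 threshold = weights$threshold,
                 quantile = weights$quantile),
            class = "ContextGEM")
}

#' @export
print.ContextGEM <- function(x, ...) {
  cat("ContextGEM [", x$context$key, "]: ",
      n_reactions(x$model), " reactions (",
      length(x$removed_reactions), " removed, ",
      length(x$reinserted_reactions), " reinserted), biomass ",
      format(x$biomass_rate, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Rate of fresh-weight increase
#'
#' First differences of the fresh-weight series per condition:
#' `(FW(t2) - FW(t1)) / (t2 - t1)` in g/day over successive measured days.
#' Non-consecutive day gaps are permitted (the rate is computed over the
#' actual interval) and flagged.
#'
#' @param growth data.frame with columns `condition`, `day`,
#'   `fresh_weight_g` (positive).
#' @return data.frame with `condition`, `day` (interval end day), `rate`
#'   (g/day), `dt`, `gap` (TRUE when `dt > 1`).
#' @export
fresh_weight_rate <- function(growth) {
  req <- c("condition", "day", "fresh_weight_g")
  if (!all(req %in% names(growth))) {
    stop("growth table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(growth$fresh_weight_g <= 0)) stop("fresh weights must be positive")
  out <- lapply(split(growth, growth$condition), function(g) {
    g <- g[order(g$day), ]
    if (nrow(g) < 2) stop("need at least two days per condition")
    dt <- diff(g$day)
    data.frame(condition = g$condition[-1], day = g$day[-1],
               rate = diff(g$fresh_weight_g) / dt, dt = dt, gap = dt > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.minmax <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

# Similarity between simulated biomass and observed growth-rate
# trajectories over the shared (condition, day) pairs: Pearson correlation,
# with RMSE after min-max scaling as tie-breaker.
.trajectory_score <- function(sim, obs) {
  if (length(sim) == 0) return(list(score = NA_real_, rmse = NA_real_))
  if (length(sim) < 2 || stats::sd(sim) == 0 || stats::sd(obs) == 0) {
    return(list(score = NA_real_,
                rmse = sqrt(mean((.minmax(sim) - .minmax(obs))^2))))
  }
  list(score = stats::cor(sim, obs),
       rmse = sqrt(mean((.minmax(sim) - .minmax(obs))^2)))
}

#' Tailor context-specific models across a quantile grid
#'
#' For each candidate threshold quantile, tailors one context model per
#' (condition, day) with GIMME and simulates its biomass production rate;
#' the quantile whose simulated trajectory best matches the observed rate
#' of fresh-weight increase (Pearson correlation; ties broken by min-max
#' scaled RMSE, then by the smaller quantile) is selected, and its models
#' are returned together with the full sweep report.
#'
#' The growth rate over `(d-1, d]` is paired with the simulated biomass of
#' day `d`; trajectories are concatenated across conditions in
#' alphabetical condition order, days ascending.
#'
#' @param model the (global) parent `MetabolicModel`.
#' @param expr an [expression_series()] covering every context.
#' @param growth growth table (see [fresh_weight_rate()]).
#' @param q_grid numeric vector of quantiles to sweep (default 0.70-0.90
#'   in steps of 0.01).
#' @param objective_fraction GIMME objective floor (default 0.9).
#' @param pool quantile pool: `"reaction"` (default) pools reaction-mapped
#'   expression over all contexts; `"gene"` pools gene-level values.
#' @param zero_tol flux zero tolerance for reinsertion.
#' @return list with `gems` (named list of `ContextGEM` at the selected
#'   quantile) and `report` (class `TailoringReport`): per-quantile
#'   thresholds, scores, feasibility, simulated trajectories, the observed
#'   rate trajectory, and the selected quantile.
#' @export
tailor_all <- function(model, expr, growth,
                       q_grid = seq(0.70, 0.90, by = 0.01),
                       objective_fraction = 0.9,
                       pool = c("reaction", "gene"),
                       zero_tol = GEM_ZERO_TOL) {
  pool <- match.arg(pool)
  stopifnot(inherits(expr, "ExpressionSeries"), length(q_grid) >= 1)
  contexts <- expr$contexts[order(expr$contexts$condition,
                                  expr$contexts$day), ]
  rxn_mat <- reaction_expression_matrix(model, expr)
  pooled <- if (pool == "reaction") as.vector(rxn_mat) else
    as.vector(expr$values)

  parent <- fba(model)
  if (parent$status != "optimal") stop("global model FBA is ", parent$status)
  zstar <- parent$objective_value
  if (zstar <= 0) stop("global model has a non-positive biomass optimum")

  rates <- fresh_weight_rate(growth)
  obs_key <- context_key(rates$condition, rates$day)

  sweep <- vector("list", length(q_grid))
  for (qi in seq_along(q_grid)) {
    q <- q_grid[qi]
    thr <- quantile_threshold(pooled, q)
    gems <- vector("list", nrow(contexts))
    names(gems) <- contexts$key
    feasible <- TRUE
    for (k in seq_len(nrow(contexts))) {
      key <- contexts$key[k]
      wts <- gimme_weights(rxn_mat[, key], thr, quantile = q)
      sol <- tryCatch(
        gimme_lp(model, wts, objective_fraction, parent_objective = zstar),
        error = function(e) NULL)
      if (is.null(sol)) { feasible <- FALSE; break }
      gems[[key]] <- extract_context_gem(model, wts, sol,
                                         contexts[k, c("condition", "day")],
                                         objective_fraction,
                                         parent_objective = zstar,
                                         zero_tol = zero_tol)
    }
    if (!feasible) {
      sweep[[qi]] <- list(quantile = q, threshold = thr, feasible = FALSE,
                          score = NA_real_, rmse = NA_real_, gems = NULL,
                          biomass = NULL)
      next
    }
    biomass <- vapply(gems, function(g) g$biomass_rate, numeric(1))
    pair <- obs_key %in% names(biomass)
    sim <- unname(biomass[obs_key[pair]])
    obs <- rates$rate[pair]
    sc <- .trajectory_score(sim, obs)
    sweep[[qi]] <- list(quantile = q, threshold = thr, feasible = TRUE,
                        score = sc$score, rmse = sc$rmse, gems = gems,
                        biomass = biomass)
  }

  scores <- vapply(sweep, function(s) s$score, numeric(1))
  rmses <- vapply(sweep, function(s) s$rmse, numeric(1))
  feas <- vapply(sweep, function(s) s$feasible, logical(1))
  if (!any(feas)) stop("no quantile in the grid yielded a feasible tailoring")
  cand <- which(feas)
  if (any(!is.na(scores[cand]))) {
    best_score <- max(scores[cand], na.rm = TRUE)
    cand <- cand[!is.na(scores[cand]) & scores[cand] >= best_score - 1e-9]
    best_rmse <- min(rmses[cand])
    cand <- cand[rmses[cand] <= best_rmse + 1e-9]
  }
  sel <- cand[1L]

  report <- structure(list(
    per_quantile = data.frame(
      quantile = q_grid,
      threshold = vapply(sweep, function(s) s$threshold, numeric(1)),
      feasible = feas, score = scores, rmse = rmses),
    trajectories = lapply(sweep, function(s) s$biomass),
    observed = rates,
    selected_quantile = q_grid[sel],
    selected_threshold = sweep[[sel]]$threshold,
    objective_fraction = objective_fraction,
    parent_objective = zstar,
    pool = pool,
    similarity = "pearson (tie: min-max scaled RMSE, then smaller quantile)"),
    class = "TailoringReport")
  list(gems = sweep[[sel]]$gems, report = report)
}

#' @export
print.TailoringReport <- function(x, ...) {
  cat("TailoringReport: ", nrow(x$per_quantile), " quantiles swept, ",
      "selected q = ", x$selected_quantile,
      " (threshold ", format(x$selected_threshold, digits = 4), ")\n",
      sep = "")
  invisible(x)
}
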