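# Cross-context comparison: flux / flux-sum matrices, drought-to-control
# fold-changes, correlation clustering of time profiles, and model census
# summaries.
#
# "Flux size" is the absolute magnitude |v|: signed fluxes would make the
# drought/control ratio ill-defined when a reversible reaction changes
# direction. Direction reversals are tracked separately in a sidecar table.

#' Assemble a flux magnitude matrix across contexts
#'
#' One row per context, one column per reaction appearing in any context
#' model. Entries are |v|; a reaction absent from a context's model is
#' imputed with one-tenth of the smallest positive magnitude observed
#' anywhere in the matrix, and zero fluxes of present reactions are floored
#' to the same value so that ratios stay finite. Both kinds of filled cell
#' are recorded.
#'
#' @param solutions named list (context key -> [flux_solution()]).
#' @param memberships named list (context key -> character vector of the
#'   reaction ids present in that context's model).
#' @return object of class `FluxMatrix`: `values` (contexts x items),
#'   `fill_mask` (imputed: absent from the context model), `floor_mask`
#'   (present but zero flux), `fill_value`, and `reversals` (data.frame of
#'   sign changes relative to the first context).
#' @export
build_flux_matrix <- function(solutions, memberships) {
  stopifnot(length(solutions) >= 1,
            all(names(solutions) %in% names(memberships)))
  keys <- names(solutions)
  items <- sort(unique(unlist(memberships[keys], use.names = FALSE)))
  vals <- matrix(NA_real_, nrow = length(keys), ncol = length(items),
                 dimnames = list(keys, items))
  signs <- vals
  for (k in keys) {
    v <- solutions[[k]]$fluxes
    present <- intersect(items, memberships[[k]])
    vals[k, present] <- abs(v[present])
    signs[k, present] <- sign(v[present])
  }
  pos <- vals[!is.na(vals) & vals > 0]
  if (!length(pos)) stop("all flux magnitudes are zero; fill value undefined")
  fill <- min(pos) / 10
  fill_mask <- is.na(vals)
  floor_mask <- !is.na(vals) & vals == 0
  vals[fill_mask | floor_mask] <- fill

  # direction reversals (informational sidecar)
  rev_list <- lapply(items, function(it) {
    s <- signs[, it]
    s <- s[!is.na(s) & s != 0]
    if (length(unique(s)) > 1) it else NULL
  })
  reversals <- data.frame(item = unlist(rev_list), stringsAsFactors = FALSE)

  structure(list(values = vals, fill_mask = fill_mask,
                 floor_mask = floor_mask, fill_value = fill,
                 reversals = reversals),
            class = "FluxMatrix")
}

#' Flux-sum matrix across contexts
#'
#' As [build_flux_matrix()], but entries are metabolite flux-sums
#' ([flux_sum()]) and columns are the union of metabolites over all
#' context models.
#'
#' @param solutions named list (context key -> [flux_solution()]).
#' @param models named list (context key -> `MetabolicModel` or
#'   `ContextGEM`).
#' @return a `FluxMatrix` over metabolites.
#' @export
flux_sum_matrix <- function(solutions, models) {
  keys <- names(solutions)
  models <- lapply(models[keys], function(m) {
    if (inherits(m, "ContextGEM")) m$model else m
  })
  fs <- lapply(keys, function(k) flux_sum(solutions[[k]], models[[k]]))
  names(fs) <- keys
  memberships <- lapply(models, function(m) m$metabolites$id)
  items <- sort(unique(unlist(memberships, use.names = FALSE)))
  vals <- matrix(NA_real_, nrow = length(keys), ncol = length(items),
                 dimnames = list(keys, items))
  for (k in keys) vals[k, names(fs[[k]])] <- fs[[k]]
  pos <- vals[!is.na(vals) & vals > 0]
  if (!length(pos)) stop("all flux-sums are zero; fill value undefined")
  fill <- min(pos) / 10
  fill_mask <- is.na(vals)
  floor_mask <- !is.na(vals) & vals == 0
  vals[fill_mask | floor_mask] <- fill
  structure(list(values = vals, fill_mask = fill_mask,
                 floor_mask = floor_mask, fill_value = fill,
                 reversals = data.frame(item = character(0))),
            class = "FluxMatrix")
}

#' Log2 fold-change between conditions for one day
#'
#' `log2(treatment / reference)` per item, computed on the filled matrix
#' (hence finite everywhere); items with a fold-change above `factor` or
#' below `1/factor` are flagged.
#'
#' @param fm a `FluxMatrix`.
#' @param day integer day.
#' @param conditions length-2 character: `c(treatment, reference)`
#'   (default `c("drought", "control")`).
#' @param factor flag threshold on the ratio scale (default 2).
#' @return data.frame: `item`, `log2fc`, `flagged`, `imputed_treatment`,
#'   `imputed_reference` (imputed or floored cells).
#' @export
fold_change <- function(fm, day, conditions = c("drought", "control"),
                        factor = 2) {
  stopifnot(inherits(fm, "FluxMatrix"), length(conditions) == 2, factor > 1)
  kt <- context_key(conditions[1], day)
  kr <- context_key(conditions[2], day)
  miss <- setdiff(c(kt, kr), rownames(fm$values))
  if (length(miss)) {
    stop("context(s) absent from the matrix: ", paste(miss, collapse = ", "))
  }
  lfc <- log2(fm$values[kt, ] / fm$values[kr, ])
  filled <- fm$fill_mask | fm$floor_mask
  # inclusive flag: a ratio of exactly `factor` counts as changed
  data.frame(item = colnames(fm$values), log2fc = unname(lfc),
             flagged = unname(abs(lfc) >= log2(factor) - 1e-12),
             imputed_treatment = unname(filled[kt, ]),
             imputed_reference = unname(filled[kr, ]),
             stringsAsFactors = FALSE)
}

#' Fold-change profiles over a day range
#'
#' Stacks [fold_change()] across days into an items x days log2
#' fold-change matrix plus the matching flag matrix.
#'
#' @inheritParams fold_change
#' @param days integer vector of days.
#' @return list with `log2fc` (items x days), `flagged` (logical), and
#'   `filtered`: the sub-matrix of items flagged on at least one day.
#' @export
fold_change_profiles <- function(fm, days, conditions = c("drought", "control"),
                                 factor = 2) {
  fcs <- lapply(days, function(d) fold_change(fm, d, conditions, factor))
  lfc <- do.call(cbind, lapply(fcs, `[[`, "log2fc"))
  flg <- do.call(cbind, lapply(fcs, `[[`, "flagged"))
  dimnames(lfc) <- dimnames(flg) <- list(fcs[[1]]$item, paste0("day", days))
  list(log2fc = lfc, flagged = flg,
       filtered = lfc[rowSums(flg) > 0, , drop = FALSE])
}

#' Cluster fold-change time profiles
#'
#' Agglomerative clustering of item profiles with distance `1 - Pearson r`
#' and average linkage, cut at distance 0.5 (profiles correlating above 0.5
#' end up in one cluster). Constant profiles, whose correlation is
#' undefined, become singleton clusters. Cluster labels are 1..K ordered by
#' decreasing size, ties broken by the alphabetically first member id.
#'
#' @param profiles numeric matrix, items (rows, named) x days.
#' @param cut correlation cut (distance `1 - cut`), default 0.5.
#' @return object of class `ClusterAssignment`: `cluster` (named integer),
#'   `hclust` (the tree over non-constant items, or NULL), `constant`
#'   (ids of constant-profile singletons).
#' @export
cluster_profiles <- function(profiles, cut = 0.5) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2,
            !is.null(rownames(profiles)))
  sds <- apply(profiles, 1, stats::sd)
  const <- rownames(profiles)[sds == 0]
  varying <- profiles[sds > 0, , drop = FALSE]
  tree <- NULL
  memb <- integer(0)
  if (nrow(varying) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(varying)))
    tree <- stats::hclust(d, method = "average")
    memb <- stats::cutree(tree, h = 1 - cut)
  } else if (nrow(varying) == 1) {
    memb <- stats::setNames(1L, rownames(varying))
  }
  # append constant profiles as singletons
  if (length(const)) {
    nxt <- if (length(memb)) max(memb) else 0L
    memb <- c(memb, stats::setNames(nxt + seq_along(const), const))
  }
  # relabel: size desc, then first member id asc
  sizes <- table(memb)
  firsts <- vapply(names(sizes), function(cl) {
    min(names(memb)[memb == cl])
  }, character(1))
  ord <- order(-as.integer(sizes), firsts)
  relab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  cluster <- stats::setNames(relab[as.character(memb)], names(memb))
  cluster <- cluster[rownames(profiles)]
  structure(list(cluster = cluster, hclust = tree, constant = const,
                 cut = cut),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment:", length(x$cluster), "items in",
      length(unique(x$cluster)), "clusters (correlation cut", x$cut, ")\n")
  invisible(x)
}

#' Occurrence percentage of reported metabolites in a context model
#'
#' The percentage of experimentally reported metabolites that are present
#' in a context-specific model, among those present in the global model
#' (reported metabolites absent from the global model are excluded from
#' numerator and denominator alike).
#'
#' @param context_gem a `ContextGEM` or `MetabolicModel`.
#' @param reported character vector of reported metabolite ids.
#' @param global the global `MetabolicModel`.
#' @return percentage in `[0, 100]`.
#' @export
occurrence_percentage <- function(context_gem, reported, global) {
  m <- if (inherits(context_gem, "ContextGEM")) context_gem$model else
    context_gem
  eligible <- intersect(unique(reported), global$metabolites$id)
  if (!length(eligible)) {
    stop("no reported metabolite is present in the global model")
  }
  100 * length(intersect(eligible, m$metabolites$id)) / length(eligible)
}

#' Census of a set of context-specific models
#'
#' Tabulates, per context, total reaction and metabolite counts and
#' per-subsystem reaction counts; per day with both conditions, the
#' condition-specific and common reaction and metabolite sets.
#'
#' @param context_gems list of `ContextGEM` objects.
#' @return object of class `ModelCensus`: `summary` (per-context counts),
#'   `subsystems` (subsystem x context reaction counts), and
#'   `condition_specific` (per day: reactions/metabolites only in one
#'   condition's model).
#' @export
model_census <- function(context_gems) {
  stopifnot(length(context_gems) >= 1)
  keys <- vapply(context_gems, function(g) g$context$key, character(1))
  names(context_gems) <- keys
  summary <- data.frame(
    context = keys,
    condition = vapply(context_gems, function(g) g$context$condition, character(1)),
    day = vapply(context_gems, function(g) g$context$day, integer(1)),
    reactions = vapply(context_gems, function(g) n_reactions(g$model), integer(1)),
    metabolites = vapply(context_gems, function(g) n_metabolites(g$model), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  subsys <- sort(unique(unlist(lapply(context_gems, function(g)
    g$model$reactions$subsystem))))
  submat <- vapply(context_gems, function(g) {
    tab <- table(factor(g$model$reactions$subsystem, levels = subsys))
    as.integer(tab)
  }, integer(length(subsys)))
  submat <- matrix(submat, nrow = length(subsys),
                   dimnames = list(subsys, keys))

  conds <- sort(unique(summary$condition))
  spec <- list()
  if (length(conds) == 2) {
    for (d in sort(unique(summary$day))) {
      k1 <- context_key(conds[1], d)
      k2 <- context_key(conds[2], d)
      if (!all(c(k1, k2) %in% keys)) next
      r1 <- context_gems[[k1]]$model$reactions$id
      r2 <- context_gems[[k2]]$model$reactions$id
      m1 <- context_gems[[k1]]$model$metabolites$id
      m2 <- context_gems[[k2]]$model$metabolites$id
      spec[[as.character(d)]] <- list(
        day = d,
        reactions = stats::setNames(
          list(setdiff(r1, r2), setdiff(r2, r1), intersect(r1, r2)),
          c(conds, "common")),
        metabolites = stats::setNames(
          list(setdiff(m1, m2), setdiff(m2, m1), intersect(m1, m2)),
          c(conds, "common")))
    }
  }
  structure(list(summary = summary, subsystems = submat,
                 condition_specific = spec),
            class = "ModelCensus")
}
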