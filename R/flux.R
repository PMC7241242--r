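# Flux balance analysis and derived screens.
#
# fba() maximizes the biomass objective c'v subject to the steady-state
# constraint S v = 0 and flux bounds l <= v <= u. Because alternate optima
# are the rule rather than the exception in genome-scale models,
# fba_min_norm() additionally selects, among optimal flux vectors, the one
# of minimal squared Euclidean norm. The regularization is implemented as a
# two-stage solve (LP for the optimum Z*, then a QP minimizing ||v||^2
# subject to c'v >= Z* (1 - min_norm)), which at the default min_norm of
# 1e-6 is equivalent to subtracting the scaled squared norm from the
# objective but is numerically better behaved.

# |v| above this counts as "carries flux" (shared with the tailoring step).
GEM_ZERO_TOL <- 1e-9

#' Construct a flux solution
#' @param fluxes named numeric vector of fluxes (model units).
#' @param objective_value objective value Z.
#' @param status `"optimal"`, `"infeasible"` or `"unbounded"`.
#' @return object of class `FluxSolution`.
#' @export
flux_solution <- function(fluxes, objective_value, status) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status),
            class = "FluxSolution")
}

#' @export
print.FluxSolution <- function(x, ...) {
  cat("FluxSolution: status =", x$status,
      "| objective =", format(x$objective_value), "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the model's objective (biomass) flux by linear programming.
#' Infeasible and unbounded problems are reported through the solution
#' status, not as errors.
#'
#' @param model a `MetabolicModel` with one objective reaction.
#' @param knockout optional reaction ids whose bounds are zeroed before
#'   solving (in-silico deletion).
#' @return a [flux_solution()].
#' @export
fba <- function(model, knockout = NULL) {
  objective_reaction(model)       # asserts a single objective
  S <- stoichiometric_matrix(model)
  bd <- .solver_bounds(model, knockout)
  obj <- model$reactions$objective_coefficient
  res <- lp_solve(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, sense = "max")
  flux_solution(stats::setNames(res$x, model$reactions$id),
                res$objval, res$status)
}

# Drop linearly dependent rows (metabolites) so the QP equality block is
# full rank; quadprog rejects redundant equality constraints.
.independent_rows <- function(S) {
  if (nrow(S) == 0) return(S)
  qrS <- qr(t(S))
  S[sort(qrS$pivot[seq_len(qrS$rank)]), , drop = FALSE]
}

#' Norm-regularized flux balance analysis
#'
#' Among flux vectors attaining the FBA optimum (within a relative
#' tolerance of `min_norm`), returns the one minimizing the squared
#' Euclidean norm of the flux vector, yielding a unique, reproducible flux
#' distribution.
#'
#' @param model a `MetabolicModel`.
#' @param knockout optional reaction ids to delete first.
#' @param min_norm relative objective give-back for the regularization
#'   stage (the classic "minNorm" magnitude, default `1e-6`).
#' @param exclude_exchange if `TRUE`, exchange reactions (single-metabolite
#'   stoichiometries) are left out of the norm (given negligible weight).
#' @return a [flux_solution()]; `objective_value` is the achieved biomass
#'   flux of the regularized solution.
#' @export
fba_min_norm <- function(model, knockout = NULL, min_norm = 1e-6,
                         exclude_exchange = FALSE) {
  lp <- fba(model, knockout)
  if (lp$status != "optimal") return(lp)
  zstar <- lp$objective_value

  S <- stoichiometric_matrix(model)
  bd <- .solver_bounds(model, knockout)
  n <- nrow(model$reactions)
  lb <- pmax(bd$lb, -GEM_BIG)
  ub <- pmin(bd$ub, GEM_BIG)
  obj <- model$reactions$objective_coefficient

  # The steady-state equalities are eliminated by solving in the null
  # space of S (v = N y, N orthonormal): the reduced QP is small, strictly
  # convex and free of the active-set degeneracies that a direct
  # equality-constrained solve runs into on models whose dead-end
  # reactions are pinned at zero by S v = 0.
  qrs <- qr(t(S))
  rank <- qrs$rank
  if (rank >= n) return(lp)                 # v = 0 is the only solution
  N <- qr.Q(qrs, complete = TRUE)[, seq.int(rank + 1L, n), drop = FALSE]

  w <- rep(1, n)
  if (exclude_exchange) {
    nmet <- vapply(model$stoich, length, integer(1))
    w[nmet == 1L] <- 1e-9          # keep the reduced D positive definite
  }
  Dmat <- 2 * crossprod(N, w * N)
  Dmat <- (Dmat + t(Dmat)) / 2
  zbound <- zstar - abs(zstar) * min_norm
  # bound rows at the artificial "big" magnitude are never active at a
  # norm-minimal point; keep the genuine (finite-model) bounds only
  keep_lb <- which(lb > -0.99 * GEM_BIG)
  keep_ub <- which(ub < 0.99 * GEM_BIG)
  Amat_v <- cbind(obj, diag(1, n)[, keep_lb, drop = FALSE],
                  -diag(1, n)[, keep_ub, drop = FALSE])
  Amat <- crossprod(N, Amat_v)
  bvec <- c(zbound, lb[keep_lb], -ub[keep_ub])
  # reactions blocked by S v = 0 (dead ends) project to all-zero
  # constraint columns; they are vacuous (0 >= b with b <= 0) but trip
  # quadprog's inconsistency detection, so drop them
  nrm <- sqrt(colSums(Amat^2))
  vacuous <- nrm < 1e-10
  if (any(vacuous & bvec > 1e-7)) {
    warning("blocked reaction with a positive lower bound; QP skipped")
    return(lp)
  }
  Amat <- Amat[, !vacuous, drop = FALSE]
  bvec <- bvec[!vacuous]
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, rep(0, ncol(N)), Amat, bvec, meq = 0),
    error = function(e) NULL)
  if (is.null(sol)) {
    warning("QP regularization failed; returning the LP solution")
    return(lp)
  }
  v <- as.numeric(N %*% sol$solution)
  v[abs(v) < GEM_ZERO_TOL] <- 0
  flux_solution(stats::setNames(v, model$reactions$id), sum(obj * v),
                "optimal")
}

#' Flux-sum of a metabolite
#'
#' Half the sum of the absolute stoichiometry-weighted fluxes of all
#' reactions touching the metabolite; under steady state this equals the
#' total production (= consumption) rate and is a proxy for turnover.
#'
#' @param solution a [flux_solution()] (status `"optimal"`).
#' @param model the `MetabolicModel` the solution was computed on.
#' @param metabolite_id metabolite id(s); default all metabolites.
#' @return named numeric vector of flux-sums.
#' @export
flux_sum <- function(solution, model, metabolite_id = NULL) {
  if (solution$status != "optimal") stop("flux_sum needs an optimal solution")
  if (is.null(metabolite_id)) metabolite_id <- model$metabolites$id
  unknown <- setdiff(metabolite_id, model$metabolites$id)
  if (length(unknown)) {
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  }
  S <- stoichiometric_matrix(model)
  v <- solution$fluxes[colnames(S)]
  fs <- 0.5 * rowSums(abs(S * rep(v, each = nrow(S))))
  fs[metabolite_id]
}

#' Single-reaction deletion screen
#'
#' Deletes each reaction in turn (both bounds set to zero), re-runs FBA and
#' classifies the effect on the biomass objective. The objective reaction
#' itself is included for completeness (its deletion is lethal by
#' construction).
#'
#' @param model a `MetabolicModel`.
#' @param reactions reaction ids to screen (default: all).
#' @param tol relative tolerance for "unchanged" and "zero" calls.
#' @return data.frame with columns `reaction_id`,
#'   `objective_after_deletion`, `essentiality_class`
#'   (`no_effect` / `reduced` / `lethal`).
#' @export
single_reaction_deletion <- function(model, reactions = NULL, tol = 1e-6) {
  wt <- fba(model)
  if (wt$status != "optimal") stop("wild-type FBA is ", wt$status)
  zwt <- wt$objective_value
  if (is.null(reactions)) reactions <- model$reactions$id
  zdel <- vapply(reactions, function(r) {
    s <- fba(model, knockout = r)
    if (s$status == "optimal") s$objective_value else 0
  }, numeric(1))
  scale <- max(abs(zwt), 1)
  cls <- ifelse(zdel <= tol * scale, "lethal",
                ifelse(zdel >= zwt - tol * scale, "no_effect", "reduced"))
  data.frame(reaction_id = reactions, objective_after_deletion = zdel,
             essentiality_class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Insert a reaction and compare objectives
#'
#' Adds a reaction (new metabolites are created as needed), runs FBA before
#' and after, and returns both objective values. Since feasible sets only
#' grow, the objective cannot decrease beyond numerical tolerance.
#'
#' @param model a `MetabolicModel`.
#' @param rxn a [reaction()] to insert.
#' @param replace overwrite an existing reaction of the same id (default
#'   `FALSE`: duplicate ids are an error).
#' @return list with `objective_before`, `objective_after` and `model`
#'   (the augmented model).
#' @export
insert_reaction_and_evaluate <- function(model, rxn, replace = FALSE) {
  before <- fba(model)
  aug <- .add_reaction(model, rxn, replace = replace)
  after <- fba(aug)
  list(objective_before = before$objective_value,
       objective_after = after$objective_value,
       model = aug)
}

#' Export a flux solution
#'
#' @param solution a [flux_solution()].
#' @param path output file.
#' @param format `"tsv"` (reaction_id, flux) or `"json"` (fluxes plus
#'   status and objective).
#' @return `path`, invisibly.
#' @export
write_flux_solution <- function(solution, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(reaction_id = names(solution$fluxes),
                     flux = unname(solution$fluxes))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(status = solution$status,
                              objective_value = solution$objective_value,
                              fluxes = as.list(solution$fluxes)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
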