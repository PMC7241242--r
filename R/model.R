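# Core representation of a genome-scale metabolic model (GEM).
#
# A MetabolicModel is a plain list with:
#   id           model identifier
#   metabolites  data.frame: id, name, compartment, external_id
#   reactions    data.frame: id, name, reversible, lower_bound, upper_bound,
#                subsystem, gene_association, objective_coefficient
#   stoich       named list (one entry per reaction id) of named numeric
#                vectors: metabolite id -> signed coefficient (< 0 substrate)
#   compartments named character vector: code -> display name
#
# Metabolites are compartment-resolved: the same chemical species in two
# compartments is two distinct metabolite ids.

#' Construct a metabolic model
#'
#' Low-level constructor; validates referential integrity between the
#' stoichiometry table and the metabolite list.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   and optionally `external_id` (e.g. a KEGG compound id).
#' @param reactions data.frame with columns `id`, `name`, `reversible`,
#'   `lower_bound`, `upper_bound`, `subsystem`, `gene_association`,
#'   `objective_coefficient`. An empty string gene association means the
#'   reaction has no known gene (common for transporters).
#' @param stoich named list, one named numeric vector per reaction id
#'   (metabolite id -> signed coefficient).
#' @param compartments named character vector of compartment codes.
#' @return object of class `MetabolicModel`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoich,
                            compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$external_id)) metabolites$external_id <- NA_character_
  if (is.null(compartments)) {
    cc <- unique(metabolites$compartment)
    compartments <- stats::setNames(cc, cc)
  }
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions, stoich = stoich,
                      compartments = compartments),
                 class = "MetabolicModel")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, bound sanity, and that every stoichiometry entry
#' resolves to a declared metabolite.
#' @param model a `MetabolicModel`.
#' @return the model, invisibly; errors describe the offending reaction.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  if (!setequal(names(model$stoich), rxn_ids)) {
    stop("stoichiometry list does not match the reaction table")
  }
  bad <- model$reactions$lower_bound > model$reactions$upper_bound
  if (any(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rxn_ids[bad], collapse = ", "))
  }
  for (r in rxn_ids) {
    sto <- model$stoich[[r]]
    if (!length(sto)) stop("reaction ", r, " has empty stoichiometry")
    unknown <- setdiff(names(sto), met_ids)
    if (length(unknown)) {
      stop("reaction ", r, " references undeclared species: ",
           paste(unknown, collapse = ", "))
    }
  }
  comp_bad <- setdiff(model$metabolites$compartment, names(model$compartments))
  if (length(comp_bad)) {
    stop("undeclared compartment code(s): ", paste(comp_bad, collapse = ", "))
  }
  invisible(model)
}

#' Number of reactions / metabolites in a model
#' @param model a `MetabolicModel`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' Id of the objective (biomass) reaction
#'
#' In pipeline use exactly one reaction carries a nonzero objective
#' coefficient: the biomass drain.
#' @param model a `MetabolicModel`.
#' @return reaction id (character scalar).
#' @export
objective_reaction <- function(model) {
  ids <- model$reactions$id[model$reactions$objective_coefficient != 0]
  if (length(ids) != 1L) {
    stop("expected exactly one objective reaction, found ", length(ids))
  }
  ids
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat("MetabolicModel <", x$id, ">\n", sep = "")
  cat("  reactions:   ", n_reactions(x), "\n", sep = "")
  cat("  metabolites: ", n_metabolites(x), "\n", sep = "")
  cat("  compartments:", paste(names(x$compartments), collapse = ", "), "\n")
  obj <- x$reactions$id[x$reactions$objective_coefficient != 0]
  cat("  objective:   ", if (length(obj)) paste(obj, collapse = ", ")
      else "<none>", "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Entry (i, j) is the signed coefficient of metabolite i in reaction j,
#' with rows ordered as the model's metabolite table and columns as its
#' reaction table. Coefficients are reported exactly as defined, without
#' renormalization.
#'
#' @param model a `MetabolicModel`.
#' @return dense numeric matrix (metabolites x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(rxn_ids)) {
    sto <- model$stoich[[rxn_ids[j]]]
    S[names(sto), j] <- sto
  }
  S
}

#' Remove preset flux constraints from a model
#'
#' Replaces all bound constraints by the widest bounds consistent with each
#' reaction's declared reversibility: irreversible reactions get `[0, Inf)`,
#' reversible reactions get `(-Inf, Inf)`. Stoichiometry, gene associations,
#' subsystems and the objective are untouched; the input model is not
#' modified. Applying the operation twice equals applying it once.
#'
#' @param model a `MetabolicModel`.
#' @return a new `MetabolicModel` with stripped constraints.
#' @export
strip_constraints <- function(model) {
  rev <- model$reactions$reversible
  model$reactions$lower_bound <- ifelse(rev, -Inf, 0)
  model$reactions$upper_bound <- Inf
  model
}

#' Build a reaction description
#'
#' Convenience constructor for a single reaction, used when inserting
#' reactions into a model or assembling models programmatically.
#'
#' @param id reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param name display name.
#' @param reversible logical.
#' @param lower_bound,upper_bound flux bounds (mmol/gDW/h by convention).
#' @param subsystem pathway label.
#' @param gene_association boolean gene rule (`""` = none).
#' @param objective_coefficient contribution to the objective.
#' @return a list of class `Reaction`.
#' @export
reaction <- function(id, stoichiometry, name = id, reversible = FALSE,
                     lower_bound = if (reversible) -Inf else 0,
                     upper_bound = Inf, subsystem = "",
                     gene_association = "", objective_coefficient = 0) {
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 reversible = reversible, lower_bound = lower_bound,
                 upper_bound = upper_bound, subsystem = subsystem,
                 gene_association = gene_association,
                 objective_coefficient = objective_coefficient),
            class = "Reaction")
}

# Add a Reaction to a model; unseen metabolites are added with a compartment
# guessed from the id suffix ("x_c" -> "c"), falling back to the first
# declared compartment.
.add_reaction <- function(model, rxn, replace = FALSE) {
  stopifnot(inherits(rxn, "Reaction"))
  if (rxn$id %in% model$reactions$id) {
    if (!replace) {
      stop("reaction id already present: ", rxn$id,
           " (use replace = TRUE to overwrite)")
    }
    model <- .remove_reactions(model, rxn$id, prune = FALSE)
  }
  new_mets <- setdiff(names(rxn$stoichiometry), model$metabolites$id)
  if (length(new_mets)) {
    comp <- sub("^.*_([^_]+)$", "\\1", new_mets)
    comp[!comp %in% names(model$compartments)] <- names(model$compartments)[1L]
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = new_mets, name = new_mets, compartment = comp,
                 external_id = NA_character_, stringsAsFactors = FALSE))
  }
  model$reactions <- rbind(model$reactions,
    data.frame(id = rxn$id, name = rxn$name, reversible = rxn$reversible,
               lower_bound = rxn$lower_bound, upper_bound = rxn$upper_bound,
               subsystem = rxn$subsystem,
               gene_association = rxn$gene_association,
               objective_coefficient = rxn$objective_coefficient,
               stringsAsFactors = FALSE))
  model$stoich[[rxn$id]] <- rxn$stoichiometry
  validate_model(model)
  model
}

# Drop reactions by id; optionally prune metabolites that no remaining
# reaction touches (orphans).
.remove_reactions <- function(model, ids, prune = TRUE) {
  keep <- !model$reactions$id %in% ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoich <- model$stoich[model$reactions$id]
  if (prune) {
    used <- unique(unlist(lapply(model$stoich, names), use.names = FALSE))
    mkeep <- model$metabolites$id %in% used
    model$metabolites <- model$metabolites[mkeep, , drop = FALSE]
    rownames(model$metabolites) <- NULL
  }
  model
}

# Bounds actually handed to a solver: reaction deletions are realized by
# zeroing both bounds without touching the network structure.
.solver_bounds <- function(model, knockout = NULL) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(knockout)) {
    idx <- match(knockout, model$reactions$id)
    if (anyNA(idx)) {
      stop("unknown reaction id(s): ",
           paste(knockout[is.na(idx)], collapse = ", "))
    }
    lb[idx] <- 0
    ub[idx] <- 0
  }
  list(lb = lb, ub = ub)
}

#' Compare two models structurally
#'
#' Equality of metabolite/reaction tables (up to row order), stoichiometries
#' and compartments; used mainly to assert SBML round-trips.
#' @param a,b `MetabolicModel` objects.
#' @return logical.
#' @export
models_equal <- function(a, b) {
  norm <- function(m) {
    mets <- m$metabolites[order(m$metabolites$id),
                          c("id", "name", "compartment", "external_id")]
    rownames(mets) <- NULL
    rxns <- m$reactions[order(m$reactions$id), ]
    rownames(rxns) <- NULL
    sto <- lapply(m$stoich[order(names(m$stoich))], function(s) s[order(names(s))])
    list(mets = mets, rxns = rxns, sto = sto,
         comp = m$compartments[order(names(m$compartments))])
  }
  isTRUE(all.equal(norm(a), norm(b), tolerance = 1e-9))
}
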