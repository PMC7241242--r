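# SBML input/output.
#
# Reading supports the two dialects that matter for this pipeline:
#  * Level 2 "COBRA style": bounds and objective coefficients as kineticLaw
#    parameters (LOWER_BOUND / UPPER_BOUND / OBJECTIVE_COEFFICIENT), gene
#    associations and subsystems in the reaction notes body as
#    "GENE_ASSOCIATION:" / "SUBSYSTEM:" paragraphs. This is the dialect used
#    by classic plant GEM distributions.
#  * Level 3 with the fbc extension: bounds as model-level parameters
#    referenced by fbc:lowerFluxBound/fbc:upperFluxBound, gene associations
#    as fbc:geneProductAssociation trees, the objective as an fbc objective
#    list. Subsystems are still probed from notes (the files this package
#    targets carry them there, not in the groups extension).
#
# Writing emits the Level 2 COBRA dialect, which `read_gem()` round-trips
# bit-faithfully at the model level. Infinite bounds are serialized as the
# XML schema doubles "INF"/"-INF".

.sbml_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  inf <- !is.na(x) & is.na(out)
  out[inf] <- ifelse(toupper(x[inf]) == "INF", Inf,
                     ifelse(toupper(x[inf]) == "-INF", -Inf, NA_real_))
  out
}

.fmt_num <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "INF", "-INF"),
         formatC(x, format = "g", digits = 15))
}

.notes_field <- function(node, key) {
  ps <- xml2::xml_find_all(node, ".//notes//*[local-name()='p']")
  txt <- xml2::xml_text(ps)
  pat <- paste0("^\\s*", key, "\\s*:")
  hit <- grep(pat, txt)
  if (!length(hit)) return("")
  trimws(sub(pat, "", txt[hit[1L]]))
}

#' Read a genome-scale metabolic model from SBML
#'
#' Parses SBML Level 2 (COBRA-style notes and kineticLaw bound parameters)
#' or Level 3 with the fbc extension. Gene-association and subsystem strings
#' are preserved verbatim. An optional two-column TSV (`model id`,
#' `external id`) attaches external (e.g. KEGG) metabolite identifiers
#' without any network access.
#'
#' @param path path to an SBML file.
#' @param external_id_map optional path to a two-column TSV mapping
#'   metabolite ids to external identifiers.
#' @return a [metabolic_model()] object.
#' @export
read_gem <- function(path, external_id_map = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML: ",
                                           conditionMessage(e), call. = FALSE))
  level <- xml2::xml_attr(doc, "level")
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, "./model")
  if (is.na(xml2::xml_name(model_node))) stop("SBML file has no <model>")
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  comp_nodes <- xml2::xml_find_all(model_node, "./listOfCompartments/compartment")
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  comp_names <- xml2::xml_attr(comp_nodes, "name")
  comp_names[is.na(comp_names)] <- comp_ids[is.na(comp_names)]
  compartments <- stats::setNames(comp_names, comp_ids)

  sp_nodes <- xml2::xml_find_all(model_node, "./listOfSpecies/species")
  sp_bound <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  keep <- is.na(sp_bound) | sp_bound %in% c("false", "0")
  sp_nodes <- sp_nodes[keep]
  metabolites <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    external_id = vapply(sp_nodes, function(n) {
      v <- .notes_field(n, "KEGG")
      if (nzchar(v)) v else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE)
  metabolites$name[is.na(metabolites$name)] <- metabolites$id[is.na(metabolites$name)]

  # model-level parameters (L3/fbc bound style)
  par_nodes <- xml2::xml_find_all(model_node, "./listOfParameters/parameter")
  par_vals <- stats::setNames(.sbml_num(xml2::xml_attr(par_nodes, "value")),
                              xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(xml2::xml_attr(gp_nodes, "label"),
                              xml2::xml_attr(gp_nodes, "id"))

  obj_coeff_fbc <- character(0)
  fo <- xml2::xml_find_all(model_node, ".//*[local-name()='fluxObjective']")
  if (length(fo)) {
    obj_coeff_fbc <- stats::setNames(
      .sbml_num(xml2::xml_attr(fo, "coefficient")),
      xml2::xml_attr(fo, "reaction"))
  }

  rx_nodes <- xml2::xml_find_all(model_node, "./listOfReactions/reaction")
  n <- length(rx_nodes)
  rid <- xml2::xml_attr(rx_nodes, "id")
  rname <- xml2::xml_attr(rx_nodes, "name")
  rname[is.na(rname)] <- rid[is.na(rname)]
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible")
  reversible <- is.na(rev_attr) | rev_attr %in% c("true", "1")

  stoich <- vector("list", n)
  lb <- numeric(n); ub <- numeric(n); objc <- numeric(n)
  subsystem <- character(n); gpr <- character(n)
  met_ids <- metabolites$id

  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    react <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    coef <- function(nodes, sign) {
      if (!length(nodes)) return(numeric(0))
      st <- xml2::xml_attr(nodes, "stoichiometry")
      st[is.na(st)] <- "1"
      stats::setNames(sign * as.numeric(st), xml2::xml_attr(nodes, "species"))
    }
    sto <- c(coef(react, -1), coef(prod, +1))
    sto <- tapply(sto, names(sto), sum)        # merge duplicate refs
    sto <- stats::setNames(as.numeric(sto), names(sto))
    unknown <- setdiff(names(sto), met_ids)
    if (length(unknown)) {
      stop("reaction ", rid[i], " references undeclared species: ",
           paste(unknown, collapse = ", "))
    }
    stoich[[i]] <- sto

    # bounds: kineticLaw parameters (L2) or fbc attributes (L3)
    kl_par <- xml2::xml_find_all(node, "./kineticLaw/listOfParameters/parameter")
    kl <- stats::setNames(.sbml_num(xml2::xml_attr(kl_par, "value")),
                          xml2::xml_attr(kl_par, "id"))
    lfb <- xml2::xml_attr(node, "lowerFluxBound")
    ufb <- xml2::xml_attr(node, "upperFluxBound")
    lb[i] <- if (!is.na(lfb)) par_vals[[lfb]]
             else if ("LOWER_BOUND" %in% names(kl)) kl[["LOWER_BOUND"]]
             else if (reversible[i]) -Inf else 0
    ub[i] <- if (!is.na(ufb)) par_vals[[ufb]]
             else if ("UPPER_BOUND" %in% names(kl)) kl[["UPPER_BOUND"]]
             else Inf
    objc[i] <- if (rid[i] %in% names(obj_coeff_fbc)) obj_coeff_fbc[[rid[i]]]
               else if ("OBJECTIVE_COEFFICIENT" %in% names(kl))
                 kl[["OBJECTIVE_COEFFICIENT"]]
               else 0

    subsystem[i] <- .notes_field(node, "SUBSYSTEM")
    gpa <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    gpr[i] <- if (!is.na(xml2::xml_name(gpa))) {
      .fbc_gpr_string(xml2::xml_children(gpa)[[1L]], gp_label)
    } else {
      .notes_field(node, "GENE_?ASSOCIATION")
    }
  }
  names(stoich) <- rid

  reactions <- data.frame(id = rid, name = rname, reversible = reversible,
                          lower_bound = lb, upper_bound = ub,
                          subsystem = subsystem, gene_association = gpr,
                          objective_coefficient = objc,
                          stringsAsFactors = FALSE)
  model <- metabolic_model(model_id, metabolites, reactions, stoich,
                           compartments)
  if (!is.null(external_id_map)) {
    map <- utils::read.delim(external_id_map, header = FALSE,
                             col.names = c("id", "external_id"),
                             stringsAsFactors = FALSE)
    hit <- match(model$metabolites$id, map$id)
    model$metabolites$external_id <- ifelse(!is.na(hit),
                                            map$external_id[hit],
                                            model$metabolites$external_id)
  }
  attr(model, "sbml_level") <- level
  model
}

# Render an fbc association tree back into the boolean-string form.
.fbc_gpr_string <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lbl <- gp_label[ref]
    return(unname(ifelse(is.na(lbl), ref, lbl)))
  }
  parts <- vapply(xml2::xml_children(node), .fbc_gpr_string, character(1),
                  gp_label = gp_label)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a model to an SBML file
#'
#' Serializes to SBML Level 2 in the COBRA-style dialect (bounds and
#' objective coefficients as kineticLaw parameters, gene association and
#' subsystem in notes). [read_gem()] on the result reproduces the model.
#'
#' @param model a `MetabolicModel`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_gem <- function(model, path) {
  validate_model(model)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" xmlns:html="http://www.w3.org/1999/xhtml" level="2" version="1">',
    sprintf('  <model id="%s">', .xml_escape(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" name="%s"/>',
            .xml_escape(names(model$compartments)),
            .xml_escape(unname(model$compartments))),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    met <- model$metabolites[i, ]
    notes <- if (!is.na(met$external_id)) {
      sprintf('><notes><html:body><html:p>KEGG: %s</html:p></html:body></notes></species>',
              .xml_escape(met$external_id))
    } else "/>"
    out <- c(out, sprintf('      <species id="%s" name="%s" compartment="%s"%s',
                          .xml_escape(met$id), .xml_escape(met$name),
                          .xml_escape(met$compartment), notes))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    sto <- model$stoich[[rx$id]]
    subs <- names(sto)[sto < 0]
    prods <- names(sto)[sto > 0]
    sref <- function(ids, vals) {
      sprintf('          <speciesReference species="%s" stoichiometry="%s"/>',
              .xml_escape(ids), .fmt_num(abs(vals)))
    }
    out <- c(out,
      sprintf('      <reaction id="%s" name="%s" reversible="%s">',
              .xml_escape(rx$id), .xml_escape(rx$name),
              tolower(as.character(rx$reversible))),
      '        <notes><html:body>',
      sprintf('          <html:p>GENE_ASSOCIATION: %s</html:p>',
              .xml_escape(rx$gene_association)),
      sprintf('          <html:p>SUBSYSTEM: %s</html:p>',
              .xml_escape(rx$subsystem)),
      '        </html:body></notes>',
      if (length(subs)) c('        <listOfReactants>',
                          sref(subs, sto[subs]),
                          '        </listOfReactants>'),
      if (length(prods)) c('        <listOfProducts>',
                           sref(prods, sto[prods]),
                           '        </listOfProducts>'),
      '        <kineticLaw>',
      '          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>',
      '          <listOfParameters>',
      sprintf('            <parameter id="LOWER_BOUND" value="%s" units="mmol_per_gDW_per_hr"/>',
              .fmt_num(rx$lower_bound)),
      sprintf('            <parameter id="UPPER_BOUND" value="%s" units="mmol_per_gDW_per_hr"/>',
              .fmt_num(rx$upper_bound)),
      sprintf('            <parameter id="OBJECTIVE_COEFFICIENT" value="%s"/>',
              .fmt_num(rx$objective_coefficient)),
      '          </listOfParameters>',
      '        </kineticLaw>',
      '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>', '  </model>', '</sbml>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con = con, sep = "\n")
  invisible(path)
}
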