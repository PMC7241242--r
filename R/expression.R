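# Expression handling: replicate averaging per (condition, day) context,
# gene -> reaction mapping through boolean gene-association rules, and the
# pooled quantile threshold used by the tailoring step.

#' Context key
#'
#' Canonical label for a (condition, day) experimental context.
#' @param condition condition label (e.g. `"control"`, `"drought"`).
#' @param day integer day, 1-based.
#' @return character key, e.g. `"control_day3"`.
#' @export
context_key <- function(condition, day) {
  sprintf("%s_day%d", condition, as.integer(day))
}

#' Construct an expression series
#'
#' A replicate-averaged gene-by-context expression container. Values are on
#' the (normalized, log-scale) unit of the deposited expression table; `NA`
#' marks a gene with no usable measurement in a context.
#'
#' @param values numeric matrix, genes in rows, one column per context;
#'   column names must equal `context_key(condition, day)`.
#' @param contexts data.frame with columns `condition` and `day`, one row
#'   per column of `values`, in column order.
#' @return object of class `ExpressionSeries`.
#' @export
expression_series <- function(values, contexts) {
  stopifnot(is.matrix(values), nrow(contexts) == ncol(values))
  contexts$key <- context_key(contexts$condition, contexts$day)
  if (!identical(colnames(values), contexts$key)) {
    stop("column names of `values` must match context keys")
  }
  structure(list(values = values, contexts = contexts),
            class = "ExpressionSeries")
}

#' @export
print.ExpressionSeries <- function(x, ...) {
  cat("ExpressionSeries: ", nrow(x$values), " genes x ",
      ncol(x$values), " contexts (",
      paste(unique(x$contexts$condition), collapse = ", "), "; days ",
      min(x$contexts$day), "-", max(x$contexts$day), ")\n", sep = "")
  invisible(x)
}

#' Average replicate samples into per-context expression values
#'
#' Collapses a gene-by-sample table to a gene-by-context table by the
#' arithmetic mean over the replicates of each (condition, day) context.
#' Missing individual replicate values are dropped from the mean; a gene
#' missing in all replicates of a context stays `NA` for that context.
#'
#' @param table numeric matrix or data.frame, genes as rows, samples as
#'   columns (column names = sample ids).
#' @param sample_sheet data.frame with columns `sample_id`, `condition`,
#'   `day`, `replicate`.
#' @return an [expression_series()].
#' @export
average_replicates <- function(table, sample_sheet) {
  table <- as.matrix(table)
  req <- c("sample_id", "condition", "day", "replicate")
  if (!all(req %in% names(sample_sheet))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  }
  missing_sheet <- setdiff(colnames(table), sample_sheet$sample_id)
  if (length(missing_sheet)) {
    stop("sample(s) absent from the sample sheet: ",
         paste(missing_sheet, collapse = ", "))
  }
  contexts <- unique(sample_sheet[order(sample_sheet$condition,
                                        sample_sheet$day),
                                  c("condition", "day")])
  rownames(contexts) <- NULL
  keys <- context_key(contexts$condition, contexts$day)
  avg <- matrix(NA_real_, nrow = nrow(table), ncol = length(keys),
                dimnames = list(rownames(table), keys))
  for (i in seq_along(keys)) {
    sel <- sample_sheet$sample_id[sample_sheet$condition == contexts$condition[i] &
                                  sample_sheet$day == contexts$day[i]]
    sel <- intersect(sel, colnames(table))
    if (!length(sel)) {
      stop("context without samples in the table: ", keys[i])
    }
    avg[, i] <- rowMeans(table[, sel, drop = FALSE], na.rm = TRUE)
  }
  avg[is.nan(avg)] <- NA_real_
  expression_series(avg, contexts)
}

# ---- gene-association rule parsing --------------------------------------

# Tokenize a boolean gene rule: identifiers, AND / OR (case-insensitive),
# parentheses.
.gpr_tokens <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

# Recursive-descent parser: expr := term (OR term)* ; term := fac (AND fac)*
# fac := "(" expr ")" | gene. Returns a nested list tree or signals an error
# (caught by the caller, which logs and treats the rule as absent).
.gpr_parse <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      node <- list(op = "or", a = node, b = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_fac()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      node <- list(op = "and", a = node, b = parse_fac())
    }
    node
  }
  parse_fac <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of gene rule")
    if (t == "(") {
      take()
      node <- parse_expr()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in gene rule")
      take()
      return(node)
    }
    if (t %in% c(")") || tolower(t) %in% c("and", "or")) {
      stop("unexpected token in gene rule: ", t)
    }
    list(op = "gene", id = take())
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in gene rule")
  out
}

# Evaluate a parsed rule against named gene values. AND resolves to the
# minimum (limiting subunit of a complex), OR to the maximum (best isozyme);
# genes with NA values are ignored within an operator, and a rule whose
# genes are all NA evaluates to NA (absent).
.gpr_eval <- function(node, values) {
  if (node$op == "gene") {
    if (!node$id %in% names(values)) return(NA_real_)
    return(unname(values[[node$id]]))
  }
  a <- .gpr_eval(node$a, values)
  b <- .gpr_eval(node$b, values)
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  if (node$op == "and") min(a, b) else max(a, b)
}

#' Map gene expression values onto reactions
#'
#' Evaluates each reaction's boolean gene-association rule against a set of
#' per-gene expression values: `and` resolves to the minimum of its
#' operands, `or` to the maximum. Reactions without a gene association (or
#' with an unparsable rule, which is reported as a warning) are absent
#' (`NA`), not zero; genes without values are ignored inside a rule.
#'
#' @param model a `MetabolicModel`.
#' @param expr named numeric vector of per-gene expression values.
#' @return named numeric vector over all reactions (NA = absent).
#' @export
map_expression_to_reactions <- function(model, expr) {
  rules <- model$reactions$gene_association
  out <- stats::setNames(rep(NA_real_, nrow(model$reactions)),
                         model$reactions$id)
  for (i in seq_along(rules)) {
    rule <- rules[i]
    if (is.na(rule) || !nzchar(trimws(rule))) next
    tree <- tryCatch(.gpr_parse(.gpr_tokens(rule)), error = function(e) {
      warning("unparsable gene association for ", model$reactions$id[i],
              " (treated as absent): ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(tree)) next
    out[i] <- .gpr_eval(tree, expr)
  }
  out
}

#' Genes referenced by a model's gene associations
#' @param model a `MetabolicModel`.
#' @return character vector of gene identifiers.
#' @export
model_genes <- function(model) {
  rules <- model$reactions$gene_association
  rules <- rules[!is.na(rules) & nzchar(trimws(rules))]
  toks <- unlist(lapply(rules, .gpr_tokens), use.names = FALSE)
  sort(unique(toks[!toks %in% c("(", ")") & !tolower(toks) %in% c("and", "or")]))
}

#' Reaction-level expression for every context of a series
#'
#' @param model a `MetabolicModel`.
#' @param series an [expression_series()].
#' @return numeric matrix, reactions x contexts (NA = absent).
#' @export
reaction_expression_matrix <- function(model, series) {
  stopifnot(inherits(series, "ExpressionSeries"))
  keys <- series$contexts$key
  out <- matrix(NA_real_, nrow = nrow(model$reactions), ncol = length(keys),
                dimnames = list(model$reactions$id, keys))
  for (k in seq_along(keys)) {
    expr <- series$values[, k]
    names(expr) <- rownames(series$values)
    out[, k] <- map_expression_to_reactions(model, expr)
  }
  out
}

#' Quantile expression threshold
#'
#' The q-th quantile of a pool of expression values under the
#' sorted-array linear-interpolation convention (`stats::quantile` type 7).
#' In the tailoring pipeline the pool is all reaction-mapped values across
#' every context, so a single threshold is shared by all days and
#' conditions; `pool = "gene"` pools gene-level values instead.
#'
#' @param values numeric vector (NAs dropped).
#' @param q quantile in `[0, 1]`.
#' @return numeric threshold.
#' @export
quantile_threshold <- function(values, q) {
  stopifnot(length(q) == 1L, q >= 0, q <= 1)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no expression values to take a quantile of")
  unname(stats::quantile(values, probs = q, type = 7))
}
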