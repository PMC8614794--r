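#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules link gene states to reaction availability: a reaction is active
#' iff its rule evaluates TRUE with knocked-out genes set to FALSE and all
#' other genes TRUE. Rules are boolean expressions over gene identifiers with
#' `and`/`or` (case-insensitive) and parentheses; `and` binds tighter than
#' `or`, matching the convention of community genome-scale models.
#'
#' @param rule character(1). The rule string; `""` or `NA` means the reaction
#'   has no gene association (always active).
#' @return A parse tree: `NULL` for an empty rule, a character(1) gene id for
#'   a leaf, or `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error: trailing input at token '", st$toks[st$pos],
         "' in rule: ", rule, call. = FALSE)
  }
  expr
}

gpr_tokenize <- function(rule) {
  s <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: unexpected end of rule", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    e <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("GPR parse error: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(e)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", tk, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tk
}

#' Evaluate a GPR rule under a gene knockout set
#'
#' @param expr A parse tree from [parse_gpr()], or a rule string.
#' @param knocked character vector of knocked-out gene ids.
#' @param genes optional character vector of valid gene ids; when supplied,
#'   every leaf of `expr` must be a member, otherwise a validation error is
#'   raised.
#' @return logical(1): TRUE iff the reaction remains catalysed. An empty rule
#'   evaluates TRUE (the reaction is not gene-associated).
#' @export
evaluate_gpr <- function(expr, knocked = character(), genes = NULL) {
  if (is.character(expr) && length(expr) == 1 && grepl("\\s|\\(", expr)) {
    expr <- parse_gpr(expr)
  }
  if (is.null(expr)) return(TRUE)
  eval_node <- function(node) {
    if (is.character(node)) {
      if (!is.null(genes) && !(node %in% genes)) {
        stop("GPR references unknown gene: ", node, call. = FALSE)
      }
      return(!(node %in% knocked))
    }
    vals <- vapply(node$args, eval_node, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  eval_node(expr)
}

#' Collect the gene leaves of a GPR parse tree
#' @param expr parse tree from [parse_gpr()].
#' @return character vector of gene ids (possibly empty).
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character())
  if (is.character(expr)) return(expr)
  unique(unlist(lapply(expr$args, gpr_genes)))
}

# Canonical string form (AND tighter than OR, lowercase keywords) used for
# round-trip comparisons of models written in different dialects.
gpr_deparse <- function(expr) {
  if (is.null(expr)) return("")
  if (is.character(expr)) return(expr)
  parts <- vapply(expr$args, function(a) {
    s <- gpr_deparse(a)
    if (!is.character(a) && expr$op == "and" && a$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$op, " "))
}
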