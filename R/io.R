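#' Load a constraint-based model from disk
#'
#' Supported dialects: the community JSON genome-scale model schema
#' (`"json"`, as written by cobra-style toolchains), SBML Level 3 with the
#' FBC extension (`"sbml"`), and a human-editable two-table TSV dialect
#' (`"tsv"`, see [write_model()]). All flux bounds are mmol gDW^-1 h^-1.
#'
#' The biomass and ATP-demand reaction ids are resolved from the file where
#' the dialect can carry them (TSV pragmas, JSON notes, the SBML FBC active
#' objective plus a model annotation) and may be overridden by the
#' `biomass_id` / `atp_id` arguments; a model whose declared biomass or ATP
#' id cannot be resolved raises a configuration error.
#'
#' @param path file path.
#' @param format one of `"json"`, `"sbml"`, `"tsv"`; default guessed from the
#'   file extension (`.json`, `.xml`/`.sbml`, `.tsv`).
#' @param biomass_id,atp_id optional overrides for the designated reactions.
#' @param label optional model label override.
#' @return an [ft_model()].
#' @export
load_model <- function(path, format = NULL, biomass_id = NULL, atp_id = NULL,
                       label = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("json", "sbml", "tsv"))
  raw <- switch(format,
    json = read_model_json(path),
    sbml = read_model_sbml(path),
    tsv = read_model_tsv(path)
  )
  ft_model(
    metabolites = raw$metabolites,
    reactions = raw$reactions,
    stoich = raw$stoich,
    genes = raw$genes,
    biomass_id = biomass_id %||% raw$biomass_id %||%
      stop("configuration error: no biomass reaction id in ", path, call. = FALSE),
    atp_id = atp_id %||% raw$atp_id %||%
      stop("configuration error: no ATP-demand reaction id in ", path, call. = FALSE),
    label = label %||% raw$label %||% "BL"
  )
}

#' Write a model to disk
#'
#' Lossless round-trip with [load_model()]: stoichiometric coefficients,
#' bounds, gene lists and canonicalised GPR strings are preserved exactly in
#' all three dialects.
#'
#' @param model an `ft_model`.
#' @param path output file path.
#' @param format `"json"`, `"sbml"` or `"tsv"`; default guessed from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "ft_model"))
  format <- format %||% guess_format(path)
  if (!format %in% c("json", "sbml", "tsv")) {
    stop("unsupported model format: ", format, call. = FALSE)
  }
  switch(format,
    json = write_model_json(model, path),
    sbml = write_model_sbml(model, path),
    tsv = write_model_tsv(model, path)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = "json", tsv = "tsv", xml = "sbml", sbml = "sbml",
    stop("cannot guess model format from extension: ", path, call. = FALSE))
}

canonical_gpr <- function(rule) gpr_deparse(parse_gpr(rule))

stoich_from_lists <- function(met_ids, rxn_ids, entries) {
  # entries: list per reaction of named numeric coefficient vectors
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    if (length(e) == 0) next
    mi <- match(normalize_met_id(names(e)), met_ids)
    if (anyNA(mi)) {
      stop("reaction '", rxn_ids[k], "' references unknown metabolite(s): ",
           paste(names(e)[is.na(mi)], collapse = ", "), call. = FALSE)
    }
    i <- c(i, mi); j <- c(j, rep.int(k, length(e))); x <- c(x, unname(e))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

## ---- JSON (community genome-scale model schema) ----

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id, character(1)),
    name = vapply(doc$metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "", character(1)),
    stringsAsFactors = FALSE
  )
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) r$id, character(1)),
    name = vapply(doc$reactions, function(r) r$name %||% r$id, character(1)),
    lower_bound = vapply(doc$reactions, function(r) as.numeric(r$lower_bound), numeric(1)),
    upper_bound = vapply(doc$reactions, function(r) as.numeric(r$upper_bound), numeric(1)),
    gpr = vapply(doc$reactions, function(r) r$gene_reaction_rule %||% "", character(1)),
    stringsAsFactors = FALSE
  )
  entries <- lapply(doc$reactions, function(r) {
    e <- unlist(r$metabolites %||% list())
    if (is.null(e)) numeric(0) else e
  })
  notes <- doc$notes %||% list()
  list(
    metabolites = mets,
    reactions = rxns,
    stoich = stoich_from_lists(normalize_met_id(mets$id), rxns$id, entries),
    genes = vapply(doc$genes %||% list(), function(g) g$id, character(1)),
    biomass_id = notes$biomass_reaction %||% NULL,
    atp_id = notes$atp_reaction %||% NULL,
    label = doc$id %||% NULL
  )
}

write_model_json <- function(model, path) {
  S <- model$stoich
  doc <- list(
    id = model$label,
    compartments = as.list(stats::setNames(
      unique(model$metabolites$compartment), unique(model$metabolites$compartment))),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment)
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(j) {
      r <- model$reactions[j, ]
      col <- S[, j]
      nz <- which(col != 0)
      list(
        id = r$id, name = r$name,
        metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                              rownames(S)[nz])),
        lower_bound = r$lower_bound, upper_bound = r$upper_bound,
        gene_reaction_rule = canonical_gpr(r$gpr)
      )
    }),
    genes = lapply(model$genes, function(g) list(id = g, name = g)),
    notes = list(biomass_reaction = model$biomass_id,
                 atp_reaction = model$atp_id)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## ---- TSV (two tables in one file, pragma header) ----

write_model_tsv <- function(model, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "#! fluxtarget-model v1",
    paste0("#! label=", model$label),
    paste0("#! biomass=", model$biomass_id),
    paste0("#! atp=", model$atp_id),
    paste0("#! genes=", paste(model$genes, collapse = ",")),
    "#! section=metabolites",
    "id\tname\tcompartment"
  ), con)
  with(model$metabolites,
       writeLines(paste(id, name, compartment, sep = "\t"), con))
  writeLines(c("#! section=reactions",
               "id\tname\tlower_bound\tupper_bound\tgpr\tstoichiometry"), con)
  S <- model$stoich
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    col <- S[, j]
    nz <- which(col != 0)
    st <- paste(sprintf("%s:%.17g", rownames(S)[nz], as.numeric(col[nz])),
                collapse = ";")
    writeLines(paste(r$id, r$name,
                     sprintf("%.17g", r$lower_bound),
                     sprintf("%.17g", r$upper_bound),
                     canonical_gpr(r$gpr), st, sep = "\t"), con)
  }
}

read_model_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#! fluxtarget-model")) {
    stop("TSV parse error in ", path, " line 1: missing model header pragma",
         call. = FALSE)
  }
  pragma <- function(key) {
    hit <- grep(paste0("^#! ", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^#! ", key, "="), "", hit[1])
  }
  sec_met <- which(lines == "#! section=metabolites")
  sec_rxn <- which(lines == "#! section=reactions")
  if (!length(sec_met) || !length(sec_rxn)) {
    stop("TSV parse error in ", path, ": missing section pragma", call. = FALSE)
  }
  met_lines <- lines[(sec_met + 2):(sec_rxn - 1)]
  rxn_lines <- lines[(sec_rxn + 2):length(lines)]
  met_lines <- met_lines[nzchar(met_lines)]
  rxn_lines <- rxn_lines[nzchar(rxn_lines)]
  metf <- do.call(rbind, strsplit(met_lines, "\t", fixed = TRUE))
  mets <- data.frame(id = metf[, 1], name = metf[, 2], compartment = metf[, 3],
                     stringsAsFactors = FALSE)
  parts <- strsplit(rxn_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6)
  if (length(bad)) {
    stop("TSV parse error in ", path, " line ", sec_rxn + 1 + bad[1],
         ": expected 6 tab-separated fields", call. = FALSE)
  }
  rxnf <- do.call(rbind, parts)
  rxns <- data.frame(id = rxnf[, 1], name = rxnf[, 2],
                     lower_bound = as.numeric(rxnf[, 3]),
                     upper_bound = as.numeric(rxnf[, 4]),
                     gpr = rxnf[, 5], stringsAsFactors = FALSE)
  entries <- lapply(rxnf[, 6], function(st) {
    if (!nzchar(st)) return(numeric(0))
    kv <- strsplit(strsplit(st, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(kv, `[`, character(1), 1))
  })
  genes <- pragma("genes")
  list(
    metabolites = mets, reactions = rxns,
    stoich = stoich_from_lists(normalize_met_id(mets$id), rxns$id, entries),
    genes = if (is.null(genes) || !nzchar(genes)) character() else
      strsplit(genes, ",", fixed = TRUE)[[1]],
    biomass_id = pragma("biomass"), atp_id = pragma("atp"),
    label = pragma("label")
  )
}

## ---- SBML Level 3 + FBC ----

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
FT_NS <- "https://fluxtarget.invalid/model-annotation"

sbml_gpr_xml <- function(expr) {
  if (is.character(expr)) {
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>', expr))
  }
  inner <- paste(vapply(expr$args, sbml_gpr_xml, character(1)), collapse = "")
  sprintf("<fbc:%s>%s</fbc:%s>", expr$op, inner, expr$op)
}

write_model_sbml <- function(model, path) {
  S <- model$stoich
  comps <- unique(model$metabolites$compartment)
  sp <- vapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    sprintf('<species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            m$id, m$name, m$compartment)
  }, character(1))
  # one parameter per distinct bound value
  bnds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  pid <- function(v) sprintf("bnd_%d", match(v, bnds))
  pars <- sprintf('<parameter id="%s" value="%.17g" constant="true"/>',
                  vapply(bnds, pid, character(1)), bnds)
  rx <- vapply(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    col <- S[, j]
    nz <- which(col != 0)
    reac <- nz[as.numeric(col[nz]) < 0]
    prod <- nz[as.numeric(col[nz]) > 0]
    sref <- function(idx) paste(sprintf(
      '<speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
      rownames(S)[idx], abs(as.numeric(col[idx]))), collapse = "")
    tree <- model$gpr_trees[[j]]
    gpa <- if (is.null(tree)) "" else
      sprintf("<fbc:geneProductAssociation>%s</fbc:geneProductAssociation>",
              sbml_gpr_xml(tree))
    sprintf(paste0(
      '<reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
      'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      '%s%s%s</reaction>'),
      r$id, r$name, tolower(r$lower_bound < 0),
      pid(r$lower_bound), pid(r$upper_bound),
      if (length(reac)) sprintf("<listOfReactants>%s</listOfReactants>", sref(reac)) else "",
      if (length(prod)) sprintf("<listOfProducts>%s</listOfProducts>", sref(prod)) else "",
      gpa)
  }, character(1))
  gps <- sprintf('<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                 model$genes, model$genes)
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('<model id="%s" fbc:strict="true">', model$label),
    sprintf('<annotation><ft:info xmlns:ft="%s" ft:atp="R_%s" ft:label="%s"/></annotation>',
            FT_NS, model$atp_id, model$label),
    "<listOfCompartments>",
    paste(sprintf('<compartment id="%s" constant="true"/>', comps), collapse = ""),
    "</listOfCompartments>",
    "<listOfSpecies>", paste(sp, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>", paste(pars, collapse = ""), "</listOfParameters>",
    "<listOfReactions>", paste(rx, collapse = ""), "</listOfReactions>",
    if (length(model$genes))
      paste0("<fbc:listOfGeneProducts>", paste(gps, collapse = ""),
             "</fbc:listOfGeneProducts>") else "",
    sprintf(paste0(
      '<fbc:listOfObjectives fbc:activeObjective="obj">',
      '<fbc:objective fbc:id="obj" fbc:type="maximize">',
      '<fbc:listOfFluxObjectives>',
      '<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
      '</fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>'),
      model$biomass_id),
    "</model></sbml>")
  writeLines(doc, path)
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1), x)
}

sbml_parse_gpa <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(strip_prefix(xml2::xml_attr(node, "geneProduct"), "G_"))
  }
  kids <- xml2::xml_children(node)
  list(op = nm, args = lapply(kids, sbml_parse_gpa))
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS, ft = FT_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("SBML parse error in ", path, ": no <model> element", call. = FALSE)
  }
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp_nodes, "id"), "M_"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE
  )
  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                            xml2::xml_attr(par_nodes, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  ids <- strip_prefix(xml2::xml_attr(rxn_nodes, "id"), "R_")
  entries <- vector("list", length(rxn_nodes))
  gprs <- character(length(rxn_nodes))
  for (j in seq_along(rxn_nodes)) {
    node <- rxn_nodes[[j]]
    coefs <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, sprintf("./s:%s/s:speciesReference", side), ns)
      if (length(refs)) {
        sg <- if (side == "listOfReactants") -1 else 1
        v <- sg * as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        names(v) <- strip_prefix(xml2::xml_attr(refs, "species"), "M_")
        coefs <- c(coefs, v)
      }
    }
    entries[[j]] <- coefs
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    gprs[j] <- if (inherits(gpa, "xml_missing")) "" else
      gpr_deparse(sbml_parse_gpa(gpa))
  }
  rxns <- data.frame(
    id = ids,
    name = xml2::xml_attr(rxn_nodes, "name"),
    lower_bound = unname(parval[xml2::xml_attr(rxn_nodes, "lowerFluxBound")]),
    upper_bound = unname(parval[xml2::xml_attr(rxn_nodes, "upperFluxBound")]),
    gpr = gprs, stringsAsFactors = FALSE
  )
  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- strip_prefix(xml2::xml_attr(gp_nodes, "id"), "G_")
  obj_ref <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  biomass_id <- if (inherits(obj_ref, "xml_missing")) NULL else
    strip_prefix(xml2::xml_attr(obj_ref, "reaction"), "R_")
  info <- xml2::xml_find_first(doc, ".//ft:info", ns)
  atp_id <- if (inherits(info, "xml_missing")) NULL else
    strip_prefix(xml2::xml_attr(info, "atp"), "R_")
  list(
    metabolites = mets, reactions = rxns,
    stoich = stoich_from_lists(normalize_met_id(mets$id), ids, entries),
    genes = genes, biomass_id = biomass_id, atp_id = atp_id,
    label = xml2::xml_attr(model_node, "id")
  )
}
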