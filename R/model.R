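#' Construct a constraint-based metabolic model
#'
#' The container used throughout the package: a stoichiometric matrix over
#' compartment-resolved metabolites, per-reaction flux bounds
#' (mmol gDW^-1 h^-1), GPR rules, and designated biomass and ATP-demand
#' reactions. Metabolite ids carry a compartment suffix, either `"_x"` or
#' `"[x]"`; both are accepted and normalised to `"_x"`. The suffix-stripped
#' `base_species` pools one chemical species across compartments for
#' metabolite-flow analysis and metabolite-centric targeting.
#'
#' @param metabolites data.frame with columns `id` and optionally `name`,
#'   `compartment` (recovered from the id suffix when missing).
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, and optionally `gpr` (rule strings) and `name`.
#' @param stoich numeric matrix or sparse Matrix, metabolites x reactions,
#'   with dimnames matching the two tables (rows may be a subset ordering).
#' @param genes character vector of gene ids; defaults to the union of all
#'   GPR leaves.
#' @param biomass_id,atp_id reaction ids of the biomass and ATP-demand
#'   reactions; must exist.
#' @param label model label, conventionally `"CA"` (cancer), `"BL"`
#'   (basal/normal) or `"HT"` (healthy).
#' @return An object of class `ft_model`.
#' @export
ft_model <- function(metabolites, reactions, stoich, genes = NULL,
                     biomass_id, atp_id, label = "BL") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids", call. = FALSE)

  metabolites$id <- normalize_met_id(metabolites$id)
  cp <- split_met_id(metabolites$id)
  if (is.null(metabolites$compartment) || all(!nzchar(metabolites$compartment))) {
    metabolites$compartment <- cp$compartment
  }
  if (any(!nzchar(metabolites$compartment))) {
    stop("metabolite(s) without a compartment: ",
         paste(metabolites$id[!nzchar(metabolites$compartment)], collapse = ", "),
         call. = FALSE)
  }
  metabolites$base_species <- cp$base
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""

  if (any(reactions$lower_bound > reactions$upper_bound)) {
    stop("reaction with lower_bound > upper_bound", call. = FALSE)
  }

  stoich <- Matrix::Matrix(stoich, sparse = TRUE)
  rownames(stoich) <- normalize_met_id(rownames(stoich))
  if (!setequal(rownames(stoich), metabolites$id) ||
      !setequal(colnames(stoich), reactions$id)) {
    stop("stoichiometry dimnames do not match metabolite/reaction tables",
         call. = FALSE)
  }
  stoich <- stoich[metabolites$id, reactions$id, drop = FALSE]

  gpr_trees <- lapply(reactions$gpr, parse_gpr)
  leaf_genes <- unique(unlist(lapply(gpr_trees, gpr_genes)))
  if (is.null(genes)) genes <- leaf_genes
  missing_genes <- setdiff(leaf_genes, genes)
  if (length(missing_genes)) {
    stop("GPR leaf gene(s) absent from gene list: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }

  if (!biomass_id %in% reactions$id) {
    stop("configuration error: biomass reaction '", biomass_id,
         "' not in model", call. = FALSE)
  }
  if (!atp_id %in% reactions$id) {
    stop("configuration error: ATP-demand reaction '", atp_id,
         "' not in model", call. = FALSE)
  }

  m <- structure(list(
    label = label,
    metabolites = metabolites,
    reactions = reactions,
    stoich = stoich,
    genes = genes,
    gpr_trees = gpr_trees,
    biomass_id = biomass_id,
    atp_id = atp_id
  ), class = "ft_model")
  m
}

#' @export
print.ft_model <- function(x, ...) {
  cat(sprintf(
    "<ft_model '%s'> %d metabolites x %d reactions, %d genes\n  biomass: %s  atp: %s\n",
    x$label, nrow(x$metabolites), nrow(x$reactions), length(x$genes),
    x$biomass_id, x$atp_id))
  invisible(x)
}

# "glc[e]" -> "glc_e"; already-normalised ids pass through.
normalize_met_id <- function(ids) {
  sub("\\[([A-Za-z0-9]+)\\]$", "_\\1", ids)
}

split_met_id <- function(ids) {
  has <- grepl("_[A-Za-z0-9]+$", ids)
  base <- ifelse(has, sub("_[A-Za-z0-9]+$", "", ids), ids)
  comp <- ifelse(has, sub("^.*_([A-Za-z0-9]+)$", "\\1", ids), "")
  list(base = base, compartment = comp)
}

#' Exchange (boundary) reactions of a model
#'
#' A reaction is an exchange/boundary reaction iff its stoichiometric column
#' touches exactly one metabolite. Exchange reactions are excluded from the
#' internal set over which the flux-minimization objective and the deviation
#' grades are computed.
#'
#' @param model an `ft_model`.
#' @return logical vector over reactions (TRUE = exchange).
#' @export
is_exchange <- function(model) {
  Matrix::colSums(model$stoich != 0) == 1
}

#' Internal (non-boundary) reaction ids
#' @param model an `ft_model`.
#' @return character vector of internal reaction ids.
#' @export
internal_reactions <- function(model) {
  model$reactions$id[!is_exchange(model)]
}

#' Split reversible reactions into forward/backward flux slots
#'
#' Every reaction i contributes a non-negative forward slot and a
#' non-negative backward slot with net flux `v_i = vf_i - vb_i`. The forward
#' slot gets bounds `[max(0, lb_i), max(0, ub_i)]` and the backward slot
#' `[max(0, -ub_i), max(0, -lb_i)]`, so irreversible reactions get a backward
#' slot fixed at zero. Any feasible net-flux vector of the parent maps to a feasible
#' (vf, vb) pair and optimal linear objectives are unchanged by the split.
#'
#' @param model an `ft_model`.
#' @return An object of class `ft_split` with per-slot bound vectors
#'   (`vf_lb`, `vf_ub`, `vb_lb`, `vb_ub`), the internal-reaction mask, and
#'   the parent model.
#' @export
split_reversible <- function(model) {
  stopifnot(inherits(model, "ft_model"))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  structure(list(
    parent = model,
    rxn_ids = model$reactions$id,
    vf_lb = pmax(0, lb),
    vf_ub = pmax(0, ub),
    vb_lb = pmax(0, -ub),
    vb_ub = pmax(0, -lb),
    internal = !is_exchange(model)
  ), class = "ft_split")
}

#' @export
print.ft_split <- function(x, ...) {
  cat(sprintf("<ft_split of '%s'> %d reactions -> %d flux slots (%d internal rxns)\n",
              x$parent$label, length(x$rxn_ids), 2L * length(x$rxn_ids),
              sum(x$internal)))
  invisible(x)
}

#' Stoichiometric matrix of a split model
#'
#' Returns `N` with one row per compartment-resolved metabolite and one
#' signed column pair per reaction, ordered `[vf_1..vf_n, vb_1..vb_n]`, so
#' that steady state reads `N %*% c(vf, vb) = 0`, i.e. `S vf - S vb = 0`.
#'
#' @param split an `ft_split`.
#' @return sparse Matrix of dimension `|metabolites| x 2|reactions|`.
#' @export
stoichiometric_matrix <- function(split) {
  stopifnot(inherits(split, "ft_split"))
  S <- split$parent$stoich
  N <- cbind(S, -S)
  if (ncol(S) > 0) {
    colnames(N) <- c(paste0(split$rxn_ids, "_f"), paste0(split$rxn_ids, "_b"))
  }
  N
}

# Index helpers: slot order is [vf (1..n), vb (n+1..2n)].
slot_index <- function(split, rxn_id, direction = c("f", "b")) {
  direction <- match.arg(direction)
  i <- match(rxn_id, split$rxn_ids)
  if (is.na(i)) stop("unknown reaction: ", rxn_id, call. = FALSE)
  if (direction == "f") i else i + length(split$rxn_ids)
}

slot_bounds <- function(split) {
  list(lb = c(split$vf_lb, split$vb_lb), ub = c(split$vf_ub, split$vb_ub))
}

#' Net flux vector from a solved flux state
#' @param state an `ft_flux_state` (see [solve_fba()]).
#' @return named numeric vector of net fluxes per reaction.
#' @export
net_flux <- function(state) {
  v <- state$vf - state$vb
  names(v) <- state$rxn_ids
  v
}
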