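#' Describe one intervention target
#'
#' Targets come in three kinds: `gene` (knockout/repression propagated
#' through GPR rules), `reaction` (direct bound modulation), and
#' `metabolite` (antimetabolite-style blocking of a species' synthesis, or a
#' supplement-style enhancement of it). For `inhibit` mode `strength` is the
#' fraction of the original bound retained (0 = full knockout, the default);
#' for `enhance` mode it is the enhancement factor (>= 0) relative to the
#' template rate.
#'
#' @param kind `"gene"`, `"reaction"` or `"metabolite"`.
#' @param id gene id, reaction id, or base species name.
#' @param mode `"inhibit"` or `"enhance"`.
#' @param strength see above.
#' @return an `ft_target`.
#' @export
target <- function(kind = c("gene", "reaction", "metabolite"), id,
                   mode = c("inhibit", "enhance"), strength = NULL) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (is.null(strength)) strength <- if (mode == "inhibit") 0 else 1.5
  if (mode == "inhibit" && (strength < 0 || strength > 1)) {
    stop("inhibit strength must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "enhance" && strength < 0) {
    stop("enhancement factor must be >= 0", call. = FALSE)
  }
  if (kind == "gene" && mode == "enhance") {
    stop("enhance mode is defined for reaction and metabolite targets only",
         call. = FALSE)
  }
  structure(list(kind = kind, id = id, mode = mode, strength = strength),
            class = "ft_target")
}

#' Parse a compact target descriptor
#'
#' Descriptors look like `"gene:HMGCR"`, `"rxn:ENO:inhibit:0.5"`,
#' `"met:dtmp:inhibit"`, `"met:fol:enhance:1.5"`. The kind prefix accepts
#' `gene`, `rxn`/`reaction`, `met`/`metabolite`.
#'
#' @param x character descriptor.
#' @return an `ft_target`.
#' @export
parse_target <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(p) < 2) stop("bad target descriptor: ", x, call. = FALSE)
  kind <- switch(p[1], gene = "gene", rxn = "reaction", reaction = "reaction",
                 met = "metabolite", metabolite = "metabolite",
                 stop("bad target kind in descriptor: ", x, call. = FALSE))
  target(kind, p[2],
         mode = if (length(p) >= 3) p[3] else "inhibit",
         strength = if (length(p) >= 4) as.numeric(p[4]) else NULL)
}

#' @export
format.ft_target <- function(x, ...) {
  sprintf("%s:%s:%s:%g", x$kind, x$id, x$mode, x$strength)
}

#' @export
print.ft_target <- function(x, ...) {
  cat("<ft_target>", format(x), "\n"); invisible(x)
}

#' Bundle targets into a treatment
#'
#' @param ... `ft_target` objects (or a single list of them), at most three;
#'   duplicate (kind, id) pairs are rejected.
#' @return an `ft_treatment`.
#' @export
treatment_set <- function(...) {
  targets <- list(...)
  if (length(targets) == 1 && !inherits(targets[[1]], "ft_target")) {
    targets <- targets[[1]]
  }
  stopifnot(all(vapply(targets, inherits, logical(1), "ft_target")))
  if (length(targets) < 1 || length(targets) > 3) {
    stop("a treatment holds between one and three targets", call. = FALSE)
  }
  keys <- vapply(targets, function(t) paste(t$kind, t$id), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (kind, id) pair in treatment", call. = FALSE)
  }
  structure(list(targets = targets), class = "ft_treatment")
}

treatment_key <- function(treatment) {
  paste(sort(vapply(treatment$targets, format, character(1))), collapse = "|")
}

#' @export
format.ft_treatment <- function(x, ...) {
  paste(vapply(x$targets, format, character(1)), collapse = " + ")
}

#' @export
print.ft_treatment <- function(x, ...) {
  cat("<ft_treatment>", format(x), "\n"); invisible(x)
}

## ---- restriction sets ----

#' Construct a restriction set
#'
#' A restriction set carries (a) per-slot bound replacements
#' (`rxn_id`, `dir` in f/b, `lb`, `ub`) and (b) extra linear constraints
#' (production floors for metabolite enhancement), each a slot-coefficient
#' table plus a right-hand side for `coef' x >= rhs`.
#'
#' @param bounds data.frame with columns rxn_id, dir, lb, ub (may be empty).
#' @param extra list of `list(coef = data.frame(rxn_id, dir, coef), rhs)`.
#' @return an `ft_restrictions`.
#' @export
restriction_set <- function(bounds = NULL, extra = list()) {
  if (is.null(bounds)) {
    bounds <- data.frame(rxn_id = character(), dir = character(),
                         lb = numeric(), ub = numeric(),
                         stringsAsFactors = FALSE)
  }
  if (any(bounds$lb > bounds$ub)) {
    stop("restriction with lb > ub", call. = FALSE)
  }
  if (any(bounds$lb < 0)) {
    stop("split-slot restrictions must be non-negative", call. = FALSE)
  }
  structure(list(bounds = bounds, extra = extra), class = "ft_restrictions")
}

#' Merge restriction sets (intersection semantics)
#' @param ... `ft_restrictions` objects.
#' @return one combined `ft_restrictions`.
#' @export
merge_restrictions <- function(...) {
  rs <- list(...)
  restriction_set(
    bounds = do.call(rbind, lapply(rs, function(r) r$bounds)),
    extra = do.call(c, lapply(rs, function(r) r$extra))
  )
}

#' Translate a gene knockout/repression into bound restrictions
#'
#' Every reaction whose GPR rule evaluates FALSE with the given genes off
#' has both flux slots restricted to `[0, strength * original upper bound]`;
#' with the default `strength = 0` this is a knockout. Isozymes rescue
#' (`"g OR h"` survives knocking g alone); genes are knocked jointly, so a
#' pair that disables an OR-rule together is handled correctly.
#'
#' @param model an `ft_model`.
#' @param genes character vector of gene ids (must be in the model).
#' @param strength fraction of the original bound retained, in [0, 1].
#' @return an `ft_restrictions`.
#' @export
gene_to_restrictions <- function(model, genes, strength = 0) {
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  split <- split_reversible(model)
  hit <- which(!vapply(model$gpr_trees, evaluate_gpr, logical(1),
                       knocked = genes, genes = model$genes))
  if (!length(hit)) return(restriction_set())
  restriction_set(bounds = data.frame(
    rxn_id = rep(model$reactions$id[hit], each = 2),
    dir = rep(c("f", "b"), length(hit)),
    lb = 0,
    ub = as.numeric(rbind(strength * split$vf_ub[hit],
                          strength * split$vb_ub[hit])),
    stringsAsFactors = FALSE
  ))
}

# slot-level production coefficients of one base species, per Eq.-8-style
# accounting: forward slots of reactions with positive stoichiometry and
# backward slots of reactions with negative stoichiometry produce it.
producer_slots <- function(model, species) {
  rows <- which(model$metabolites$base_species == species)
  if (!length(rows)) {
    stop("unknown base species: ", species, call. = FALSE)
  }
  S <- model$stoich[rows, , drop = FALSE]
  coef_f <- Matrix::colSums(S * (S > 0))   # positive contributions, vf slots
  coef_b <- Matrix::colSums(-S * (S < 0))  # reverse of consumers, vb slots
  list(coef_f = as.numeric(coef_f), coef_b = as.numeric(coef_b))
}

#' Translate an antimetabolite/supplement target into restrictions
#'
#' Inhibition blocks the synthesis of the species: every internal flux slot
#' that produces it (positive stoichiometric contribution in that slot's
#' direction), across all compartments, is restricted to
#' `[0, strength * original bound]`; consuming slots are untouched.
#' Enhancement constrains the total production rate of the species to at
#' least `strength * reference_flow` (a supplement acts on the metabolite,
#' not on any one reaction), expressed as an extra linear constraint.
#'
#' @param model an `ft_model`.
#' @param species base species name (compartment-pooled).
#' @param mode `"inhibit"` or `"enhance"`.
#' @param strength bound fraction (inhibit) or enhancement factor (enhance).
#' @param reference_flow for enhance mode: the untreated normal-template
#'   production rate of the species (see [compute_templates()]).
#' @return an `ft_restrictions`.
#' @export
metabolite_to_restrictions <- function(model, species,
                                       mode = c("inhibit", "enhance"),
                                       strength = if (mode == "inhibit") 0 else 1.5,
                                       reference_flow = NULL) {
  mode <- match.arg(mode)
  ps <- producer_slots(model, species)
  split <- split_reversible(model)
  internal <- !is_exchange(model)
  prod_f <- which(ps$coef_f > 0 & internal & split$vf_ub > 0)
  prod_b <- which(ps$coef_b > 0 & internal & split$vb_ub > 0)
  if (mode == "inhibit") {
    if (!length(prod_f) && !length(prod_b)) {
      stop("species '", species, "' is not produced by any internal reaction",
           call. = FALSE)
    }
    return(restriction_set(bounds = data.frame(
      rxn_id = c(model$reactions$id[prod_f], model$reactions$id[prod_b]),
      dir = c(rep("f", length(prod_f)), rep("b", length(prod_b))),
      lb = 0,
      ub = c(strength * split$vf_ub[prod_f], strength * split$vb_ub[prod_b]),
      stringsAsFactors = FALSE
    )))
  }
  if (is.null(reference_flow)) {
    stop("enhance mode needs the template production rate (reference_flow)",
         call. = FALSE)
  }
  nzf <- which(ps$coef_f > 0)
  nzb <- which(ps$coef_b > 0)
  coef <- data.frame(
    rxn_id = c(model$reactions$id[nzf], model$reactions$id[nzb]),
    dir = c(rep("f", length(nzf)), rep("b", length(nzb))),
    coef = c(ps$coef_f[nzf], ps$coef_b[nzb]),
    stringsAsFactors = FALSE
  )
  restriction_set(extra = list(list(coef = coef,
                                    rhs = strength * reference_flow)))
}

#' Translate a reaction-centric target into restrictions
#'
#' Inhibition restricts both slots to `[0, strength * original bound]`;
#' enhancement raises the forward lower bound to
#' `strength * template net flux`.
#'
#' @param model an `ft_model`.
#' @param rxn_id reaction id.
#' @param mode `"inhibit"` or `"enhance"`.
#' @param strength bound fraction (inhibit) or flux multiple (enhance).
#' @param template_flux for enhance mode: the template net flux of the
#'   reaction.
#' @return an `ft_restrictions`.
#' @export
reaction_to_restrictions <- function(model, rxn_id,
                                     mode = c("inhibit", "enhance"),
                                     strength = if (mode == "inhibit") 0 else 1,
                                     template_flux = NULL) {
  mode <- match.arg(mode)
  j <- match(rxn_id, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", rxn_id, call. = FALSE)
  split <- split_reversible(model)
  if (mode == "inhibit") {
    return(restriction_set(bounds = data.frame(
      rxn_id = rxn_id, dir = c("f", "b"), lb = 0,
      ub = c(strength * split$vf_ub[j], strength * split$vb_ub[j]),
      stringsAsFactors = FALSE
    )))
  }
  if (is.null(template_flux)) {
    stop("enhance mode needs the template net flux (template_flux)",
         call. = FALSE)
  }
  restriction_set(bounds = data.frame(
    rxn_id = rxn_id, dir = "f",
    lb = max(0, strength * template_flux), ub = split$vf_ub[j],
    stringsAsFactors = FALSE
  ))
}

#' Build the full restriction set of a treatment for one model
#'
#' The same treatment is applied with the identical construction rule to the
#' cancer and normal model (per-model GPRs and stoichiometry decide which
#' slots it touches). Enhancement targets are referenced against the normal
#' template (`templates$bl_flow` for metabolites, the model's own template
#' flux for reactions).
#'
#' @param model an `ft_model`.
#' @param treatment an `ft_treatment`.
#' @param templates an `ft_templates` (needed for enhance-mode targets).
#' @return an `ft_restrictions`.
#' @export
treatment_restrictions <- function(model, treatment, templates = NULL) {
  stopifnot(inherits(treatment, "ft_treatment"))
  parts <- list()
  gene_targets <- Filter(function(t) t$kind == "gene", treatment$targets)
  if (length(gene_targets)) {
    strengths <- vapply(gene_targets, `[[`, numeric(1), "strength")
    parts <- c(parts, list(gene_to_restrictions(
      model, vapply(gene_targets, `[[`, character(1), "id"),
      strength = min(strengths))))
  }
  for (t in treatment$targets) {
    if (t$kind == "gene") next
    if (t$kind == "reaction") {
      tf <- NULL
      if (t$mode == "enhance") {
        if (is.null(templates)) stop("enhance target needs templates", call. = FALSE)
        tpl <- if (identical(model$label, "CA")) templates$ca else templates$bl
        tf <- unname(net_flux(tpl)[t$id])
      }
      parts <- c(parts, list(reaction_to_restrictions(
        model, t$id, t$mode, t$strength, template_flux = tf)))
    } else {
      rf <- NULL
      if (t$mode == "enhance") {
        if (is.null(templates)) stop("enhance target needs templates", call. = FALSE)
        rf <- unname(templates$bl_flow[t$id])
        if (is.na(rf)) rf <- 0
      }
      parts <- c(parts, list(metabolite_to_restrictions(
        model, t$id, t$mode, t$strength, reference_flow = rf)))
    }
  }
  do.call(merge_restrictions, parts)
}

#' Apply a restriction set to a split model
#'
#' Returns a copy with slot bounds replaced by the intersection of the
#' original interval and every restriction interval touching the slot; the
#' original split model is untouched. Extra linear constraints are attached
#' for the solvers. An empty intersection (lb > ub) is allowed here and
#' surfaces as an infeasible solve.
#'
#' @param split an `ft_split`.
#' @param restrictions an `ft_restrictions`.
#' @return a new `ft_split`.
#' @export
apply_restrictions <- function(split, restrictions) {
  stopifnot(inherits(split, "ft_split"), inherits(restrictions, "ft_restrictions"))
  out <- split
  b <- restrictions$bounds
  for (k in seq_len(nrow(b))) {
    j <- match(b$rxn_id[k], split$rxn_ids)
    if (is.na(j)) stop("restriction references unknown reaction: ",
                       b$rxn_id[k], call. = FALSE)
    if (b$dir[k] == "f") {
      out$vf_lb[j] <- max(out$vf_lb[j], b$lb[k])
      out$vf_ub[j] <- min(out$vf_ub[j], b$ub[k])
    } else {
      out$vb_lb[j] <- max(out$vb_lb[j], b$lb[k])
      out$vb_ub[j] <- min(out$vb_ub[j], b$ub[k])
    }
  }
  n <- length(split$rxn_ids)
  extras <- lapply(restrictions$extra, function(e) {
    coef <- numeric(2 * n)
    idx <- match(e$coef$rxn_id, split$rxn_ids)
    if (anyNA(idx)) stop("constraint references unknown reaction", call. = FALSE)
    idx <- idx + ifelse(e$coef$dir == "b", n, 0L)
    coef[idx] <- coef[idx] + e$coef$coef
    list(coef = coef, rhs = e$rhs)
  })
  out$extra_constraints <- c(split$extra_constraints %||% list(), extras)
  out
}
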