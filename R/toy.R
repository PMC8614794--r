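#' Configuration for the paired toy-model generator
#'
#' @param n_branches number of harmless side-branch pathways (extra
#'   candidate genes for search tests).
#' @param include_warburg_shift give the cancer model a higher uptake bound
#'   and a permissive lactate-like overflow sink, so the two untreated
#'   templates differ the way tumour and normal flux patterns do.
#' @param seed integer; fixes the generated pair bit-for-bit.
#' @param planted_lethal_gene,planted_safe_gene gene ids used for the
#'   planted cancer-lethal and planted no-effect targets.
#' @return an `ft_toy_config`.
#' @export
toy_config <- function(n_branches = 3, include_warburg_shift = TRUE,
                       seed = 1L, planted_lethal_gene = "g_lethal",
                       planted_safe_gene = "g_safe") {
  stopifnot(n_branches >= 0, n_branches <= 12)
  structure(list(
    n_branches = as.integer(n_branches),
    include_warburg_shift = isTRUE(include_warburg_shift),
    seed = as.integer(seed),
    planted_lethal_gene = planted_lethal_gene,
    planted_safe_gene = planted_safe_gene
  ), class = "ft_toy_config")
}

# Direct net-flux FBA used ONLY for generator verification; deliberately
# independent of the split-model solver path both in model assembly (no
# splitting) and in algorithm (ridge-regularized quadratic program rather
# than a simplex). The tiny ridge biases the optimum by at most
# ridge * ||v||^2, well below the assertion tolerances used here.
toy_fba <- function(model, objective_rxn, knocked = character()) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  off <- !vapply(model$gpr_trees, evaluate_gpr, logical(1), knocked = knocked)
  lb[off] <- 0
  ub[off] <- 0
  cc <- as.numeric(model$reactions$id == objective_rxn)
  free <- (ub - lb) > 0  # pinned reactions are constants, not variables
  S <- as.matrix(model$stoich)
  rhs <- as.numeric(-S[, !free, drop = FALSE] %*% lb[!free])
  S <- S[, free, drop = FALSE]
  keep <- rowSums(S != 0) > 0
  if (any(abs(rhs[!keep]) > 1e-12)) return(0)  # pinned fluxes violate balance
  S <- S[keep, , drop = FALSE]; rhs <- rhs[keep]
  qd <- qr(t(S))
  pick <- qd$pivot[seq_len(qd$rank)]
  S <- S[pick, , drop = FALSE]; rhs <- rhs[pick]
  n <- sum(free)
  ridge <- 1e-7
  sol <- tryCatch(
    quadprog::solve.QP(
      Dmat = diag(2 * ridge, n), dvec = cc[free],
      Amat = t(rbind(S, diag(n), -diag(n))),
      bvec = c(rhs, lb[free], -ub[free]),
      meq = nrow(S)),
    error = function(e) NULL)
  if (is.null(sol)) return(NA_real_)
  v <- lb
  v[free] <- pmin(pmax(sol$solution, lb[free]), ub[free])
  sum(cc * v)
}

#' Generate a paired cancer/normal toy model with planted ground truth
#'
#' Both models share one reaction set: glucose uptake and transport, a
#' glycolysis-like step, an ATP-yielding step feeding an ATP demand, two
#' redundant precursor routes (the second gated by the planted safe gene), a
#' cancer-only biomass precursor synthesized through the planted lethal
#' gene's reaction, an overflow (lactate-like) branch, and `n_branches`
#' low-capacity side branches. The cancer biomass additionally consumes the
#' cancer-only precursor, so knocking the lethal gene (or the precursor's
#' synthesis reaction, or the precursor metabolite) abolishes cancer growth
#' while leaving the normal model's ATP optimum untouched. Every planted
#' property is verified by direct FBA before the pair is returned; a failed
#' verification is a generator assertion error.
#'
#' @param config an [toy_config()].
#' @return list with elements `ca`, `bl` ([ft_model()]s) and `truth`
#'   (planted target labels, anchor optima, the verifying fractions).
#' @export
make_toy_pair <- function(config = toy_config()) {
  stopifnot(inherits(config, "ft_toy_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  nb <- config$n_branches
  branch_caps <- round(stats::runif(nb, 0.5, 2), 3)

  uptake_bl <- 10
  uptake_ca <- if (config$include_warburg_shift) 20 else 10
  lac_sink_bl <- if (config$include_warburg_shift) 1 else 100
  lac_sink_ca <- 100

  mets <- data.frame(
    id = c("glc_e", "glc_c", "pyr_c", "atp_c", "prec_c", "caprec_c",
           "lac_c", "lac_e",
           if (nb > 0) sprintf("br%d_c", seq_len(nb))),
    stringsAsFactors = FALSE
  )
  mets$name <- mets$id
  base_rxns <- list(
    list(id = "SRC_glc", s = c(glc_e = 1), lb = 0, ub = NA, gpr = ""),
    list(id = "T_glc", s = c(glc_e = -1, glc_c = 1), lb = -100, ub = 100,
         gpr = "g_trans"),
    list(id = "GLY", s = c(glc_c = -1, pyr_c = 2), lb = 0, ub = 100,
         gpr = "g_gly"),
    list(id = "OXP", s = c(pyr_c = -1, atp_c = 5), lb = 0, ub = 500,
         gpr = "g_oxp"),
    list(id = "DM_atp", s = c(atp_c = -1), lb = 0, ub = 1000, gpr = ""),
    list(id = "PREC1", s = c(glc_c = -1, prec_c = 1), lb = 0, ub = 100,
         gpr = "g_prec1"),
    list(id = "PREC2", s = c(glc_c = -1, prec_c = 1), lb = 0, ub = 100,
         gpr = config$planted_safe_gene),
    list(id = "CAP", s = c(pyr_c = -1, caprec_c = 1), lb = 0, ub = 100,
         gpr = config$planted_lethal_gene),
    list(id = "LACS", s = c(pyr_c = -1, lac_c = 1), lb = 0, ub = 100,
         gpr = "g_lac"),
    list(id = "T_lac", s = c(lac_c = -1, lac_e = 1), lb = 0, ub = 100,
         gpr = ""),
    list(id = "SINK_lac", s = c(lac_e = -1), lb = 0, ub = NA, gpr = "")
  )
  for (i in seq_len(nb)) {
    base_rxns <- c(base_rxns, list(
      list(id = sprintf("BR%d", i),
           s = stats::setNames(c(-1, 1), c("glc_c", sprintf("br%d_c", i))),
           lb = 0, ub = branch_caps[i], gpr = sprintf("g_br%d", i)),
      list(id = sprintf("SINK_br%d", i),
           s = stats::setNames(-1, sprintf("br%d_c", i)),
           lb = 0, ub = branch_caps[i], gpr = "")
    ))
  }

  build <- function(label) {
    ca <- identical(label, "CA")
    rxns <- base_rxns
    bm <- c(pyr_c = -1, prec_c = -1, atp_c = -2)
    if (ca) bm <- c(bm, caprec_c = -1)
    rxns <- c(rxns, list(list(id = "BIOMASS", s = bm, lb = 0, ub = 100,
                              gpr = "")))
    rxn_df <- data.frame(
      id = vapply(rxns, `[[`, character(1), "id"),
      lower_bound = vapply(rxns, `[[`, numeric(1), "lb"),
      upper_bound = vapply(rxns, function(r) {
        if (!is.na(r$ub)) return(r$ub)
        switch(r$id,
               SRC_glc = if (ca) uptake_ca else uptake_bl,
               SINK_lac = if (ca) lac_sink_ca else lac_sink_bl)
      }, numeric(1)),
      gpr = vapply(rxns, `[[`, character(1), "gpr"),
      stringsAsFactors = FALSE
    )
    stoich <- stoich_from_lists(mets$id, rxn_df$id,
                                lapply(rxns, `[[`, "s"))
    ft_model(metabolites = mets[, c("id", "name")], reactions = rxn_df,
             stoich = stoich,
             genes = sort(unique(unlist(lapply(rxns, function(r)
               gpr_genes(parse_gpr(r$gpr)))))),
             biomass_id = "BIOMASS", atp_id = "DM_atp", label = label)
  }
  ca <- build("CA")
  bl <- build("BL")

  assert <- function(ok, what) {
    if (!isTRUE(ok)) stop("toy generator assertion failed: ", what,
                          call. = FALSE)
  }
  ca_biomass <- toy_fba(ca, "BIOMASS")
  bl_biomass <- toy_fba(bl, "BIOMASS")
  bl_atp <- toy_fba(bl, "DM_atp")
  assert(is.finite(ca_biomass) && ca_biomass > 0.1,
         "untreated CA growth optimum must be nonzero")
  assert(is.finite(bl_biomass) && bl_biomass > 0.1,
         "untreated BL growth optimum must be nonzero")
  assert(is.finite(bl_atp) && bl_atp > 1,
         "untreated BL ATP optimum must be nonzero")

  ca_ko_lethal <- toy_fba(ca, "BIOMASS", config$planted_lethal_gene)
  bl_atp_ko_lethal <- toy_fba(bl, "DM_atp", config$planted_lethal_gene)
  ca_ko_safe <- toy_fba(ca, "BIOMASS", config$planted_safe_gene)
  bl_atp_ko_safe <- toy_fba(bl, "DM_atp", config$planted_safe_gene)
  assert(ca_ko_lethal <= 1e-6,
         "planted lethal gene must abolish CA growth")
  assert(bl_atp_ko_lethal >= 0.5 * bl_atp,
         "planted lethal gene must leave BL viable (>= 50% ATP optimum)")
  assert(abs(ca_ko_safe - ca_biomass) <= 1e-4 * max(1, ca_biomass),
         "planted safe gene must not change the CA growth optimum")

  truth <- list(
    lethal_to_CA = c(
      paste0("gene:", config$planted_lethal_gene),
      "reaction:CAP",
      "metabolite:caprec"
    ),
    safe = paste0("gene:", config$planted_safe_gene),
    bl_viable_under = stats::setNames(
      c(bl_atp_ko_lethal / bl_atp, bl_atp_ko_safe / bl_atp),
      c(paste0("gene:", config$planted_lethal_gene),
        paste0("gene:", config$planted_safe_gene))),
    ca_biomass_opt = ca_biomass,
    bl_biomass_opt = bl_biomass,
    bl_atp_opt = bl_atp,
    config = unclass(config)
  )
  list(ca = ca, bl = bl, truth = truth)
}

#' Write a toy fixture pair plus its ground-truth manifest
#'
#' @param pair result of [make_toy_pair()].
#' @param dir output directory (created if missing).
#' @param format model dialect passed to [write_model()].
#' @return the directory, invisibly.
#' @export
write_fixture <- function(pair, dir, format = "json") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- switch(format, json = "json", tsv = "tsv", sbml = "xml",
                stop("unsupported model format: ", format, call. = FALSE))
  write_model(pair$ca, file.path(dir, paste0("ca.", ext)), format)
  write_model(pair$bl, file.path(dir, paste0("bl.", ext)), format)
  jsonlite::write_json(pair$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
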