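#' Objective weights for the cellular objective
#'
#' The linear cellular objective is `w_atp * v_ATP + w_biomass * v_biomass`
#' over net fluxes of the designated ATP-demand and biomass reactions.
#' Defaults used by the pipeline: cancer models maximize growth alone
#' (`atp = 0, biomass = 1`) so that mortality is judged on the growth
#' optimum, while normal models trade off ATP production and growth
#' (`atp = 1, biomass = 1`).
#'
#' @param atp,biomass non-negative weights; not both zero.
#' @return named numeric vector of class `ft_weights`.
#' @export
objective_weights <- function(atp = 0, biomass = 1) {
  if (atp < 0 || biomass < 0 || (atp == 0 && biomass == 0)) {
    stop("objective weights must be non-negative and not both zero",
         call. = FALSE)
  }
  structure(c(atp = atp, biomass = biomass), class = "ft_weights")
}

# death threshold on the biomass flux: below it a treated cancer model is
# classified dead
DEATH_THRESHOLD <- 1e-10

# relative relaxation of the objective-attainment constraint in the
# flux-minimization QP, absorbing LP/QP tolerance mismatch
UFD_DELTA <- 1e-6

# ridge weight on non-internal (exchange) flux slots in the QP Hessian;
# keeps the Hessian positive definite so the whole solution is unique while
# perturbing internal fluxes negligibly
UFD_RIDGE <- 1e-6

flux_state <- function(split, x, objective_value, status) {
  n <- length(split$rxn_ids)
  vf <- x[seq_len(n)]
  vb <- x[n + seq_len(n)]
  names(vf) <- names(vb) <- split$rxn_ids
  net <- vf - vb
  structure(list(
    rxn_ids = split$rxn_ids,
    vf = vf, vb = vb,
    objective_value = objective_value,
    status = status,
    biomass = unname(net[split$parent$biomass_id]),
    atp = unname(net[split$parent$atp_id])
  ), class = "ft_flux_state")
}

#' @export
print.ft_flux_state <- function(x, ...) {
  cat(sprintf("<ft_flux_state> status=%s obj=%.6g biomass=%.6g atp=%.6g\n",
              x$status, x$objective_value, x$biomass, x$atp))
  invisible(x)
}

empty_state <- function(split, status) {
  flux_state(split, numeric(2 * length(split$rxn_ids)), 0, status)
}

objective_coef <- function(split, weights) {
  n <- length(split$rxn_ids)
  cc <- numeric(2 * n)
  ia <- slot_index(split, split$parent$atp_id, "f")
  ib <- slot_index(split, split$parent$biomass_id, "f")
  cc[ia] <- cc[ia] + weights[["atp"]]
  cc[ib] <- cc[ib] + weights[["biomass"]]
  cc[ia + n] <- cc[ia + n] - weights[["atp"]]
  cc[ib + n] <- cc[ib + n] - weights[["biomass"]]
  cc
}

# Maximize cc'x subject to N x = 0, lb <= x <= ub, and optional extra linear
# rows coef'x >= rhs. Variables are shifted to y = x - lb >= 0, pinned slots
# (lb == ub) are eliminated, and >= rows get bounded surplus variables so the
# whole problem fits the box-constrained simplex kernel.
lp_maximize <- function(N, lb, ub, cc, extra = list()) {
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  ub <- pmax(lb, ub)  # guard tiny crossings
  Nd <- as.matrix(N)
  keep <- rowSums(Nd != 0) > 0
  Nd <- Nd[keep, , drop = FALSE]
  beq <- as.numeric(-Nd %*% lb)
  free <- (ub - lb) > 0
  Aeq <- Nd[, free, drop = FALSE]
  cc_f <- cc[free]
  ub_f <- (ub - lb)[free]
  for (e in extra) {
    rhs <- e$rhs - sum(e$coef * lb)
    coef <- e$coef[free]
    # coef'y - s = rhs with 0 <= s <= coef'(ub - lb) - rhs (slack capacity)
    s_ub <- max(0, sum(pmax(coef, 0) * ub_f) - rhs)
    Aeq <- rbind(cbind(Aeq, 0), c(coef, -1))
    beq <- c(beq, rhs)
    cc_f <- c(cc_f, 0)
    ub_f <- c(ub_f, s_ub)
  }
  res <- simplex_box_lp(cc_f, Aeq, beq, ub_f)
  if (res$status == "infeasible") {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  if (res$status != "optimal") {
    return(list(status = "error", x = NULL, value = NA_real_))
  }
  x <- lb
  x[free] <- x[free] + res$x[seq_len(sum(free))]
  list(status = "optimal", x = x, value = sum(cc * x))
}

split_with_restrictions <- function(split, restrictions) {
  if (is.null(restrictions)) return(split)
  apply_restrictions(split, restrictions)
}

#' Flux balance analysis on a split model
#'
#' Maximizes the weighted cellular objective over the steady-state flux
#' polytope `N (vf - vb) = 0` within slot bounds, after applying any
#' treatment bound restrictions. An infeasible polytope is reported as a
#' `status = "infeasible"` state with all fluxes zero (an infeasible treated
#' cancer model is maximally dead, and the fitness loop must still be able
#' to grade it). When biomass is the sole objective term and its optimum
#' falls at or below the death threshold (1e-10), status is `"dead"`.
#'
#' @param split an [split_reversible()] model.
#' @param weights an [objective_weights()].
#' @param restrictions optional `ft_restrictions` from the treatment module.
#' @return an `ft_flux_state` with `vf`, `vb`, `objective_value`, `status`.
#' @export
solve_fba <- function(split, weights = objective_weights(),
                      restrictions = NULL) {
  stopifnot(inherits(split, "ft_split"))
  s2 <- split_with_restrictions(split, restrictions)
  bb <- slot_bounds(s2)
  cc <- objective_coef(s2, weights)
  N <- stoichiometric_matrix(s2)
  res <- lp_maximize(N, bb$lb, bb$ub, cc, extra = s2$extra_constraints %||% list())
  if (res$status == "infeasible") return(empty_state(s2, "infeasible"))
  if (res$status == "error") {
    stop("LP solver failure (status ", res$status, ") in solve_fba",
         call. = FALSE)
  }
  st <- flux_state(s2, res$x, res$value, "optimal")
  if (weights[["atp"]] == 0 && weights[["biomass"]] > 0 &&
      st$biomass <= DEATH_THRESHOLD) {
    st$status <- "dead"
  }
  st
}

# Remove linearly dependent steady-state rows (rhs is 0 so dependent rows
# are consistent); the dual QP method requires independent equalities.
independent_rows <- function(M) {
  if (nrow(M) == 0) return(M)
  qr_dec <- qr(t(M))
  M[qr_dec$pivot[seq_len(qr_dec$rank)], , drop = FALSE]
}

#' Flux-minimization (unique flux distribution) problem
#'
#' At the FBA optimum the internal flux pattern is generally non-unique;
#' this second stage minimizes the sum of squared internal forward and
#' backward fluxes subject to steady state, bounds, treatment restrictions,
#' and attainment of the FBA objective (relaxed by a relative 1e-6 to absorb
#' LP/QP tolerance mismatch). Strict convexity on the internal subspace makes
#' the internal flux pattern unique; non-internal slots carry a tiny ridge
#' weight so the full solution is unique as well.
#'
#' @param split an `ft_split`.
#' @param restrictions optional `ft_restrictions` (must match those used for
#'   the FBA stage).
#' @param weights the [objective_weights()] used in the FBA stage.
#' @param obj_star the FBA optimum returned by [solve_fba()] under the same
#'   restrictions.
#' @return an `ft_flux_state`; `objective_value` is the achieved cellular
#'   objective (not the quadratic value, which is in `$quadratic`).
#' @export
solve_ufd <- function(split, restrictions = NULL,
                      weights = objective_weights(), obj_star = NULL) {
  stopifnot(inherits(split, "ft_split"), !is.null(obj_star))
  s2 <- split_with_restrictions(split, restrictions)
  bb <- slot_bounds(s2)
  if (any(bb$lb > bb$ub + 1e-12)) return(empty_state(s2, "infeasible"))
  n <- length(s2$rxn_ids)
  w <- rep(UFD_RIDGE, 2 * n)
  w[c(which(s2$internal), n + which(s2$internal))] <- 1
  cc <- objective_coef(s2, weights)
  target <- if (obj_star > 0) obj_star * (1 - UFD_DELTA) else
    obj_star - UFD_DELTA * max(1, abs(obj_star))

  N_full <- as.matrix(stoichiometric_matrix(s2))
  free <- (bb$ub - bb$lb) > 0  # pinned slots are constants, not variables
  rhs_eq <- as.numeric(-N_full[, !free, drop = FALSE] %*% bb$lb[!free])
  N <- N_full[, free, drop = FALSE]
  keep <- rowSums(N != 0) > 0
  if (any(abs(rhs_eq[!keep]) > 1e-9)) return(empty_state(s2, "infeasible"))
  N <- N[keep, , drop = FALSE]; rhs_eq <- rhs_eq[keep]
  qd <- qr(t(N))
  pick <- qd$pivot[seq_len(qd$rank)]
  N <- N[pick, , drop = FALSE]; rhs_eq <- rhs_eq[pick]

  extras <- s2$extra_constraints %||% list()
  nf <- sum(free)
  solve_at <- function(tgt) {
    Aineq <- rbind(cc[free],
                   if (length(extras))
                     do.call(rbind, lapply(extras, function(e) e$coef[free])),
                   diag(nf), -diag(nf))
    bineq <- c(tgt - sum(cc[!free] * bb$lb[!free]),
               if (length(extras)) vapply(extras, function(e)
                 e$rhs - sum(e$coef[!free] * bb$lb[!free]), numeric(1)),
               bb$lb[free], -bb$ub[free])
    tryCatch(
      quadprog::solve.QP(Dmat = diag(2 * w[free], nf),
                         dvec = numeric(nf),
                         Amat = t(rbind(N, Aineq)),
                         bvec = c(rhs_eq, bineq), meq = nrow(N)),
      error = function(e) e)
  }
  sol <- solve_at(target)
  if (inherits(sol, "error")) {
    # retry with a visibly relaxed attainment target before giving up
    relaxed <- if (obj_star > 0) obj_star * (1 - 1e-4) else
      obj_star - 1e-4 * max(1, abs(obj_star))
    sol <- solve_at(relaxed)
    if (inherits(sol, "error")) {
      stop("flux-minimization QP infeasible at the FBA optimum (",
           conditionMessage(sol), "); FBA/UFD inconsistency", call. = FALSE)
    }
  }
  x <- bb$lb
  x[free] <- pmin(pmax(sol$solution, bb$lb[free]), bb$ub[free])
  st <- flux_state(s2, x, sum(cc * x), "optimal")
  int_slots <- c(which(s2$internal), n + which(s2$internal))
  st$quadratic <- sum(x[int_slots]^2)
  st
}

#' Untreated templates for a cancer/normal model pair
#'
#' Solves FBA followed by flux minimization with an empty restriction set
#' for both models, records the untreated anchor optima used by the grading
#' module (cancer max-growth optimum, normal max-growth and max-ATP optima),
#' and computes the template metabolite-flow vectors.
#'
#' @param ca,bl `ft_model` objects for the cancer and normal cell.
#' @param weights_ca,weights_bl [objective_weights()] for each model.
#' @return an object of class `ft_templates`.
#' @export
compute_templates <- function(ca, bl,
                              weights_ca = objective_weights(0, 1),
                              weights_bl = objective_weights(1, 1)) {
  ca_split <- split_reversible(ca)
  bl_split <- split_reversible(bl)
  ca_fba <- solve_fba(ca_split, weights_ca)
  bl_fba <- solve_fba(bl_split, weights_bl)
  ca_tpl <- solve_ufd(ca_split, NULL, weights_ca, ca_fba$objective_value)
  bl_tpl <- solve_ufd(bl_split, NULL, weights_bl, bl_fba$objective_value)
  ca_biomass_opt <- solve_fba(ca_split, objective_weights(0, 1))$biomass
  bl_biomass_opt <- solve_fba(bl_split, objective_weights(0, 1))$biomass
  bl_atp_opt <- solve_fba(bl_split, objective_weights(1, 0))$atp
  structure(list(
    ca = ca_tpl, bl = bl_tpl,
    ca_fba = ca_fba, bl_fba = bl_fba,
    ca_split = ca_split, bl_split = bl_split,
    ca_flow = metabolite_flow(ca_tpl, ca),
    bl_flow = metabolite_flow(bl_tpl, bl),
    ca_biomass_opt = ca_biomass_opt,
    bl_biomass_opt = bl_biomass_opt,
    bl_atp_opt = bl_atp_opt,
    weights_ca = weights_ca, weights_bl = weights_bl
  ), class = "ft_templates")
}

#' @export
print.ft_templates <- function(x, ...) {
  cat(sprintf(paste0(
    "<ft_templates> CA biomass opt %.4g | BL biomass opt %.4g | ",
    "BL ATP opt %.4g\n"),
    x$ca_biomass_opt, x$bl_biomass_opt, x$bl_atp_opt))
  invisible(x)
}

#' Export a solved flux state as a TSV flux table
#' @param state an `ft_flux_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(state, path) {
  df <- data.frame(reaction = state$rxn_ids,
                   net_flux = state$vf - state$vb,
                   vf = state$vf, vb = state$vb)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
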