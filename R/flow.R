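#' Metabolite-flow (flux-sum) rates of a solved state
#'
#' For each base species the total production rate pooled across its
#' compartment instances: the sum over reactions with positive
#' stoichiometric coefficient of `N_ij * vf_j` minus the sum over reactions
#' with negative coefficient of `N_ij * vb_j` (i.e. production by forward
#' flux plus production by running consumers backwards). Units
#' mmol gDW^-1 h^-1; rates are non-negative for any bound-respecting state.
#'
#' @param state an `ft_flux_state`.
#' @param model the `ft_model` the state was solved on.
#' @return named non-negative numeric vector over base species.
#' @export
metabolite_flow <- function(state, model) {
  stopifnot(inherits(state, "ft_flux_state"), inherits(model, "ft_model"))
  S <- model$stoich
  pos <- S * (S > 0)
  neg <- S * (S < 0)
  per_met <- as.numeric(pos %*% state$vf) - as.numeric(neg %*% state$vb)
  tapply(per_met, model$metabolites$base_species, sum)[
    unique(model$metabolites$base_species)]
}

# consumption computed symmetrically; at steady state it must match
# production for species untouched by boundary reactions
metabolite_consumption <- function(state, model) {
  S <- model$stoich
  pos <- S * (S > 0)
  neg <- S * (S < 0)
  per_met <- as.numeric(-neg %*% state$vf) + as.numeric(pos %*% state$vb)
  tapply(per_met, model$metabolites$base_species, sum)[
    unique(model$metabolites$base_species)]
}

#' Log2 fold changes of metabolite flows against the normal template
#'
#' Each perturbation column is `log2((r + pseudo) / (r_BL + pseudo))`; an
#' optional template column does the same for the cancer template. Rows
#' where every column is zero within tolerance (unchanged flows) are
#' dropped.
#'
#' @param flows named list of flow vectors (one per perturbation), as
#'   returned by [metabolite_flow()].
#' @param bl_flow the normal-template flow vector.
#' @param template_flow optional cancer-template flow vector, appended as a
#'   column named `"template"`.
#' @param pseudo pseudo-flow guarding log2 of zero (default 1e-9).
#' @param drop_tol rows with all |L| below this are dropped (default 1e-6).
#' @return numeric matrix, species x columns.
#' @export
log2_fold_changes <- function(flows, bl_flow, template_flow = NULL,
                              pseudo = 1e-9, drop_tol = 1e-6) {
  if (is.numeric(flows)) flows <- list(perturbation = flows)
  all_flows <- c(flows, if (!is.null(template_flow))
    list(template = template_flow))
  sp <- names(bl_flow)
  for (f in all_flows) {
    if (!setequal(names(f), sp)) {
      stop("flow vectors must share the species support of the normal template",
           call. = FALSE)
    }
    if (any(f < -1e-12)) stop("negative metabolite flow", call. = FALSE)
  }
  L <- vapply(all_flows, function(f) {
    log2((pmax(f[sp], 0) + pseudo) / (pmax(bl_flow, 0) + pseudo))
  }, numeric(length(sp)))
  L <- matrix(L, nrow = length(sp),
              dimnames = list(sp, names(all_flows)))
  keep <- apply(abs(L) >= drop_tol, 1, any)
  L[keep, , drop = FALSE]
}

#' Iterated principal-factor analysis with quartimax rotation
#'
#' Extracts common factors from the correlation matrix of the fold-change
#' matrix rows (species are the variables, perturbation columns the
#' observations). Communalities start from squared multiple correlations and
#' are iterated to convergence (principal-axis factoring); the loading
#' matrix is then rotated by the orthogonal quartimax criterion, which
#' maximizes the sum of fourth powers of the loadings.
#'
#' @param x numeric matrix, variables (species) in rows, observations in
#'   columns, as produced by [log2_fold_changes()].
#' @param n_factors number of factors to extract (>= 1, < `ncol(x)`).
#' @param tol communality convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last iterate.
#' @return an `ft_factors` list: `loadings` (variables x factors, rotated),
#'   `communality`, `ss_loadings`, `prop_var` (share of total variance),
#'   `prop_common` (share of common variance), `rotation = "quartimax"`,
#'   `iterations`.
#' @export
factor_analysis <- function(x, n_factors, tol = 1e-4, max_iter = 500) {
  x <- as.matrix(x)
  if (ncol(x) < n_factors) {
    stop("need at least as many columns as factors", call. = FALSE)
  }
  if (anyNA(x)) stop("missing values in fold-change matrix", call. = FALSE)
  p <- nrow(x)
  R <- stats::cor(t(x))
  # constant rows have no variance to share
  if (anyNA(R)) {
    stop("constant rows in the matrix; drop unchanged flows first",
         call. = FALSE)
  }
  # initial communalities: squared multiple correlations (ridge-guarded)
  Rinv <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-8, p)))
  h2 <- pmin(pmax(1 - 1 / diag(Rinv), 0.1), 0.995)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Rh <- R
    diag(Rh) <- h2
    ed <- eigen(Rh, symmetric = TRUE)
    lam <- pmax(ed$values[seq_len(n_factors)], 0)
    L <- ed$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(lam), n_factors)
    h2_new <- pmin(rowSums(L^2), 0.999)
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) break
    if (iter >= max_iter) {
      err <- simpleError(sprintf(
        "principal-factor iteration did not converge in %d iterations (last delta %.3g)",
        max_iter, delta))
      err$last_loadings <- L
      stop(err)
    }
  }
  L <- quartimax_rotate(L)
  # orient factors: dominant loading positive, order by explained variance
  sgn <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, "*")
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ss <- ss[ord]
  colnames(L) <- paste0("F", seq_len(n_factors))
  rownames(L) <- rownames(x)
  structure(list(
    loadings = L,
    communality = rowSums(L^2),
    ss_loadings = ss,
    prop_var = ss / p,
    prop_common = ss / sum(ss),
    rotation = "quartimax",
    iterations = iter
  ), class = "ft_factors")
}

#' @export
print.ft_factors <- function(x, ...) {
  cat(sprintf("<ft_factors> %d variables, %d factors (%s, %d iterations)\n",
              nrow(x$loadings), ncol(x$loadings), x$rotation, x$iterations))
  cat("share of total variance:",
      paste(sprintf("%.1f%%", 100 * x$prop_var), collapse = " "), "\n")
  invisible(x)
}

# Orthogonal quartimax rotation by pairwise (Jacobi-style) planar rotations:
# for each factor pair the angle maximizing the sum of fourth powers has the
# classical closed form tan(4 phi) = D / C on the pair's loadings.
quartimax_rotate <- function(L, tol = 1e-10, max_sweeps = 100) {
  k <- ncol(L)
  if (k < 2) return(L)
  crit <- function(M) sum(M^4)
  for (sweep in seq_len(max_sweeps)) {
    before <- crit(L)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        x <- L[, a]; y <- L[, b]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- 2 * sum(u * v)
        den <- sum(u^2 - v^2)
        if (abs(num) < 1e-14 && abs(den) < 1e-14) next
        phi <- atan2(num, den) / 4
        cs <- cos(phi); sn <- sin(phi)
        L[, a] <- cs * x + sn * y
        L[, b] <- -sn * x + cs * y
      }
    }
    if (crit(L) - before < tol) break
  }
  L
}
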