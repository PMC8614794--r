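#' Evaluate one treatment against a model pair
#'
#' The inner loop of the search: builds the treatment's bound restrictions
#' for each model, solves FBA then flux minimization for the treated cancer
#' model and the perturbed normal model, and computes the full grade set.
#' Mortality is always judged on the treated cancer model's max-growth
#' optimum (an extra LP when the cancer objective is not pure growth).
#' Solver failures degrade to an all-zero-fitness grade set with a warning,
#' so a search never aborts on a pathological candidate. Results are
#' memoized by the canonicalised target set when a `cache` environment is
#' supplied.
#'
#' @param treatment an [treatment_set()].
#' @param ca,bl the cancer and normal `ft_model`.
#' @param templates an [compute_templates()] result for the pair.
#' @param cache optional environment used as a memo table.
#' @param strict propagate evaluation errors instead of degrading to zero
#'   fitness (used for explicit single-treatment grading).
#' @return an `ft_grades` with attribute `"treatment"`.
#' @export
evaluate_treatment <- function(treatment, ca, bl, templates, cache = NULL,
                               strict = FALSE) {
  key <- treatment_key(treatment)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    cache$.hits <- (cache$.hits %||% 0L) + 1L
    return(cache[[key]])
  }
  g <- if (strict) {
    evaluate_treatment_impl(treatment, ca, bl, templates)
  } else tryCatch(
    evaluate_treatment_impl(treatment, ca, bl, templates),
    error = function(e) {
      warning("treatment ", format(treatment), " failed to evaluate (",
              conditionMessage(e), "); fitness set to 0", call. = FALSE)
      failed_grades()
    })
  attr(g, "treatment") <- treatment
  if (!is.null(cache)) {
    cache[[key]] <- g
    cache$.misses <- (cache$.misses %||% 0L) + 1L
  }
  g
}

failed_grades <- function() {
  grade_set(
    eta_cvtr = 0,
    viability = list(eta_biomass_pb = 0, eta_atp_pb = 0, eta_cvpb = 0),
    deviation = list(eta_sf = 0, eta_sm = 0, eta_lf = 0, eta_lm = 0,
                     eta_v = 0, eta_m = 0, eta_dv = 0)
  )
}

evaluate_treatment_impl <- function(treatment, ca, bl, templates) {
  restr_ca <- treatment_restrictions(ca, treatment, templates)
  restr_bl <- treatment_restrictions(bl, treatment, templates)

  w_ca <- templates$weights_ca
  ca_fba <- solve_fba(templates$ca_split, w_ca, restr_ca)
  treated_biomass <- if (w_ca[["atp"]] == 0) ca_fba$biomass else
    solve_fba(templates$ca_split, objective_weights(0, 1), restr_ca)$biomass
  if (ca_fba$status == "optimal") {
    ca_state <- solve_ufd(templates$ca_split, restr_ca, w_ca,
                          ca_fba$objective_value)
  } else {
    ca_state <- ca_fba
  }

  w_bl <- templates$weights_bl
  bl_fba <- solve_fba(templates$bl_split, w_bl, restr_bl)
  if (bl_fba$status %in% c("optimal", "dead")) {
    bl_state <- solve_ufd(templates$bl_split, restr_bl, w_bl,
                          bl_fba$objective_value)
  } else {
    bl_state <- bl_fba
  }

  eta_cvtr <- grade_mortality(treated_biomass, templates$ca_biomass_opt)
  viability <- grade_perturbed_viability(bl_state, templates$bl_atp_opt,
                                         templates$bl_biomass_opt)
  deviation <- grade_deviation(bl_state, templates,
                               perturbed_flow = metabolite_flow(bl_state, bl))
  g <- grade_set(eta_cvtr, viability, deviation)
  attr(g, "ca_state") <- ca_state
  attr(g, "bl_state") <- bl_state
  g
}

#' Candidate pools for the outer search
#'
#' Multi-target searches use two candidate groups to cut the combinatorial
#' burden: the first slot of every combination draws from `group1`
#' (typically the best one-target hits of an earlier run) and the remaining
#' slots draw from `group2`. With an empty `group2` all slots share
#' `group1`.
#'
#' @param group1 list of `ft_target` (or descriptor strings).
#' @param group2 optional second list, disjoint from `group1`.
#' @return an `ft_pools`.
#' @export
candidate_pools <- function(group1, group2 = list()) {
  as_targets <- function(g) lapply(g, function(t)
    if (inherits(t, "ft_target")) t else parse_target(t))
  group1 <- as_targets(group1)
  group2 <- as_targets(group2)
  if (!length(group1)) stop("group1 must be non-empty", call. = FALSE)
  k1 <- vapply(group1, function(t) paste(t$kind, t$id), character(1))
  k2 <- vapply(group2, function(t) paste(t$kind, t$id), character(1))
  if (length(intersect(k1, k2))) {
    stop("candidate groups must be disjoint", call. = FALSE)
  }
  structure(list(group1 = group1, group2 = group2), class = "ft_pools")
}

slot_pools <- function(pools, K) {
  stopifnot(inherits(pools, "ft_pools"), K >= 1)
  if (length(pools$group2) == 0 || K == 1) {
    rep(list(pools$group1), K)
  } else {
    c(list(pools$group1), rep(list(pools$group2), K - 1))
  }
}

z_to_treatment <- function(z, sp) {
  treatment_set(lapply(seq_along(z), function(s) sp[[s]][[z[s]]]))
}

target_keys <- function(targets) {
  vapply(targets, function(t) paste(t$kind, t$id), character(1))
}

# resample duplicate slots uniformly from unused pool members
repair_z <- function(z, sp) {
  for (s in seq_along(z)) {
    keys <- target_keys(lapply(seq_along(z), function(i) sp[[i]][[z[i]]]))
    if (!anyDuplicated(keys)) break
    dup <- which(duplicated(keys))[1]
    pool_keys <- target_keys(sp[[dup]])
    free <- which(!(pool_keys %in% keys[-dup]))
    if (!length(free)) stop("pool too small to repair duplicates", call. = FALSE)
    z[dup] <- free[sample.int(length(free), 1)]
  }
  z
}

#' Search configuration for the outer differential evolution
#'
#' Population search over integer target-index vectors, fitness `eta_d`.
#' Defaults: population 20, mutation factor 0.7, crossover rate 0.8, 100
#' generations, migration (re-randomization of all but the best individual)
#' when the population's fitness spread drops below 0.01.
#'
#' @param np population size (>= 4).
#' @param f mutation factor in (0, 2].
#' @param cr crossover rate in \[0, 1\].
#' @param generations generation cap.
#' @param migration_tol fitness-spread threshold triggering migration.
#' @param seed RNG seed; the search is fully reproducible under a fixed
#'   seed.
#' @param use_cache memoize fitness by canonical target set.
#' @return an `ft_nhde_config`.
#' @export
nhde_config <- function(np = 20, f = 0.7, cr = 0.8, generations = 100,
                        migration_tol = 0.01, seed = 1L, use_cache = TRUE) {
  stopifnot(np >= 4, f > 0, f <= 2, cr >= 0, cr <= 1, generations >= 1)
  structure(list(np = as.integer(np), f = f, cr = cr,
                 generations = as.integer(generations),
                 migration_tol = migration_tol, seed = as.integer(seed),
                 use_cache = isTRUE(use_cache)),
            class = "ft_nhde_config")
}

rank_archive <- function(cache) {
  keys <- setdiff(ls(cache), c(".hits", ".misses"))
  if (!length(keys)) stop("no evaluated candidates", call. = FALSE)
  rows <- lapply(keys, function(k) {
    g <- cache[[k]]
    cbind(data.frame(treatment = format(attr(g, "treatment")), key = k,
                     stringsAsFactors = FALSE),
          as.data.frame(g))
  })
  df <- do.call(rbind, rows)
  ord <- order(-df$eta_d, -df$eta_se, df$key)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "treatments") <- lapply(keys[ord], function(k)
    attr(cache[[k]], "treatment"))
  df
}

#' Nested hybrid differential evolution over candidate targets
#'
#' Outer-level search maximizing the hierarchical fitness `eta_d`:
#' DE/rand/1 mutation with rounding and clipping to integer pool indices,
#' binomial crossover, duplicate repair, greedy selection, and a migration
#' phase that re-randomizes all but the best individual when the population
#' fitness spread collapses. Every distinct candidate evaluated anywhere in
#' the run is archived, and the archive is returned ranked by `eta_d`, ties
#' broken by `eta_se` (fewer predicted side effects) then lexicographically.
#'
#' @param ca,bl the model pair.
#' @param pools an [candidate_pools()].
#' @param K number of targets per combination (1-3).
#' @param config an [nhde_config()].
#' @param templates optional precomputed [compute_templates()].
#' @param weights_ca,weights_bl objectives used if `templates` is NULL.
#' @return ranked data.frame (one row per distinct candidate, all fourteen
#'   grades) with attribute `"treatments"`.
#' @export
run_search <- function(ca, bl, pools, K = 1, config = nhde_config(),
                       templates = NULL,
                       weights_ca = objective_weights(0, 1),
                       weights_bl = objective_weights(1, 1)) {
  sp <- slot_pools(pools, K)
  sizes <- lengths(sp)
  if (any(sizes == 0)) stop("empty candidate pool", call. = FALSE)
  templates <- templates %||% compute_templates(ca, bl, weights_ca, weights_bl)
  cache <- new.env(parent = emptyenv())

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  evalz <- function(z) {
    evaluate_treatment(z_to_treatment(z, sp), ca, bl, templates,
                       cache = if (config$use_cache) cache else NULL)
  }
  rand_z <- function() {
    repair_z(vapply(sizes, function(n) sample.int(n, 1), integer(1)), sp)
  }

  np <- config$np
  pop <- lapply(seq_len(np), function(i) rand_z())
  fit <- lapply(pop, evalz)
  eta_d <- vapply(fit, `[[`, numeric(1), "eta_d")

  for (gen in seq_len(config$generations)) {
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3)
      mutant <- pop[[r[1]]] + config$f * (pop[[r[2]]] - pop[[r[3]]])
      mutant <- pmin(pmax(round(mutant), 1L), sizes)
      jrand <- sample.int(K, 1)
      cross <- stats::runif(K) < config$cr
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[[i]])
      trial <- repair_z(as.integer(trial), sp)
      g <- evalz(trial)
      better <- g$eta_d > eta_d[i] ||
        (g$eta_d == eta_d[i] && g$eta_se > fit[[i]]$eta_se)
      if (better) {
        pop[[i]] <- trial
        fit[[i]] <- g
        eta_d[i] <- g$eta_d
      }
    }
    # migration: diversity collapse -> keep the champion, reseed the rest
    if (max(eta_d) - min(eta_d) < config$migration_tol && gen < config$generations) {
      best <- which.max(eta_d)
      for (i in setdiff(seq_len(np), best)) {
        pop[[i]] <- rand_z()
        fit[[i]] <- evalz(pop[[i]])
        eta_d[i] <- fit[[i]]$eta_d
      }
    }
  }
  if (!config$use_cache) {
    for (i in seq_len(np)) {
      g <- fit[[i]]
      cache[[treatment_key(attr(g, "treatment"))]] <- g
    }
  }
  rank_archive(cache)
}

#' Exhaustively evaluate every candidate combination
#'
#' Test oracle for [run_search()]: enumerates all valid combinations under
#' the same pooling structure (first slot from group 1, remaining slots
#' unordered from group 2, no duplicate targets) and ranks them by the same
#' rules. Guarded against combinatorial blow-up.
#'
#' @param ca,bl,pools,K,templates,weights_ca,weights_bl as in
#'   [run_search()].
#' @param max_evals guard on the number of combinations (default 5000).
#' @return ranked data.frame as in [run_search()].
#' @export
exhaustive_search <- function(ca, bl, pools, K = 1, templates = NULL,
                              weights_ca = objective_weights(0, 1),
                              weights_bl = objective_weights(1, 1),
                              max_evals = 5000) {
  sp <- slot_pools(pools, K)
  two_group <- length(pools$group2) > 0 && K >= 2
  combos <- if (K == 1) {
    lapply(seq_along(sp[[1]]), function(i) list(sp[[1]][[i]]))
  } else if (two_group) {
    out <- list()
    rest_idx <- utils::combn(length(sp[[2]]), K - 1, simplify = FALSE)
    for (i in seq_along(sp[[1]])) {
      for (js in rest_idx) {
        tg <- c(sp[[1]][i], sp[[2]][js])
        if (anyDuplicated(target_keys(tg))) next
        out <- c(out, list(tg))
      }
    }
    out
  } else {
    lapply(utils::combn(length(sp[[1]]), K, simplify = FALSE),
           function(js) sp[[1]][js])
  }
  if (length(combos) > max_evals) {
    stop("exhaustive search over ", length(combos),
         " combinations exceeds the guard of ", max_evals, call. = FALSE)
  }
  templates <- templates %||% compute_templates(ca, bl, weights_ca, weights_bl)
  cache <- new.env(parent = emptyenv())
  for (tg in combos) {
    evaluate_treatment(treatment_set(tg), ca, bl, templates, cache = cache)
  }
  rank_archive(cache)
}
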