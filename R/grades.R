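#' Linear membership specification
#'
#' Each fuzzy objective is normalised to \[0, 1\] by a linear membership
#' function between two anchors. `sense = "maximize"` gives
#' `clip((x - x0)/(x1 - x0), 0, 1)`, `sense = "minimize"` the mirror image.
#'
#' @param x0,x1 lower and upper anchors, `x0 < x1`.
#' @param sense `"maximize"` or `"minimize"`.
#' @return an `ft_membership`.
#' @export
membership_spec <- function(x0, x1, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  if (!(x0 < x1)) stop("membership anchors require x0 < x1", call. = FALSE)
  structure(list(x0 = x0, x1 = x1, sense = sense), class = "ft_membership")
}

#' Evaluate a linear membership grade
#' @param x numeric value(s).
#' @param spec an [membership_spec()].
#' @return grade(s) in \[0, 1\].
#' @export
linear_membership <- function(x, spec) {
  stopifnot(inherits(spec, "ft_membership"))
  g <- (x - spec$x0) / (spec$x1 - spec$x0)
  if (spec$sense == "minimize") g <- 1 - g
  pmin(pmax(g, 0), 1)
}

#' Mean-min aggregation of membership grades
#'
#' The fuzzy conjunction used throughout the grade hierarchy:
#' `(arithmetic mean + minimum) / 2`. It is idempotent
#' (`mean_min(a, a, ...) = a`) and squeezed between the minimum and the mean
#' of its inputs.
#'
#' @param ... grades in \[0, 1\], or a single numeric vector.
#' @return aggregated grade.
#' @export
mean_min <- function(...) {
  g <- c(...)
  if (!length(g)) stop("mean_min needs at least one grade", call. = FALSE)
  if (any(g < 0 | g > 1)) stop("grades must lie in [0, 1]", call. = FALSE)
  (mean(g) + min(g)) / 2
}

#' Mortality grade of the treated cancer cell
#'
#' Linear membership, sense minimize, anchored on
#' `[0, untreated growth optimum]`: an unaffected cancer model grades 0, a
#' dead one (growth at or below 1e-10) grades exactly 1.
#'
#' @param treated an `ft_flux_state` for the treated cancer model, or the
#'   treated biomass flux itself.
#' @param untreated_opt untreated cancer max-growth optimum (> 0).
#' @return `eta_cvtr` in \[0, 1\].
#' @export
grade_mortality <- function(treated, untreated_opt) {
  if (untreated_opt <= 0) {
    stop("untreated growth optimum must be positive", call. = FALSE)
  }
  b <- if (inherits(treated, "ft_flux_state")) treated$biomass else treated
  if (b <= DEATH_THRESHOLD) return(1)
  linear_membership(b, membership_spec(0, untreated_opt, "minimize"))
}

#' Viability grades of the perturbed normal cell
#'
#' Perturbed viability asks for high ATP production and low growth: the ATP
#' grade is a maximizing membership on `[0, untreated ATP optimum]`, the
#' growth grade a minimizing membership on `[0, untreated growth optimum]`
#' (both anchor pairs configurable), and the combined grade is their
#' mean-min.
#'
#' @param perturbed an `ft_flux_state` for the perturbed normal model.
#' @param atp_opt,biomass_opt untreated normal-model ATP and growth optima.
#' @param atp_spec,biomass_spec optional [membership_spec()] overrides.
#' @return list with `eta_atp_pb`, `eta_biomass_pb`, `eta_cvpb`.
#' @export
grade_perturbed_viability <- function(perturbed, atp_opt, biomass_opt,
                                      atp_spec = NULL, biomass_spec = NULL) {
  atp_spec <- atp_spec %||% membership_spec(0, atp_opt, "maximize")
  biomass_spec <- biomass_spec %||% membership_spec(0, biomass_opt, "minimize")
  eta_atp <- linear_membership(perturbed$atp, atp_spec)
  eta_bio <- linear_membership(perturbed$biomass, biomass_spec)
  list(eta_atp_pb = eta_atp, eta_biomass_pb = eta_bio,
       eta_cvpb = mean_min(eta_bio, eta_atp))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Metabolic-deviation grades of the perturbed normal cell
#'
#' Scores how far the perturbed flux pattern has moved away from the cancer
#' template (dissimilarity is good) while staying close to the normal
#' template (similarity is good), on both reaction fluxes and pooled
#' metabolite-flow rates. Per reaction i the deviation scale is
#' `d_i = max(|v_CA,i - v_BL,i|, eps * max(1, |v_BL,i|))`; dissimilarity
#' memberships `clip(|v_PB - v_CA| / d, 0, 1)` are averaged over reactions
#' where the cancer template runs lower than normal (`eta_sf`) and higher
#' than normal (`eta_lf`), with the same construction on metabolite flows
#' (`eta_sm`, `eta_lm`). Similarity memberships
#' `1 - clip(|v_PB - v_BL| / d, 0, 1)` are averaged over all internal
#' reactions (`eta_v`) and all species (`eta_m`). An empty partition grades
#' vacuously 1. The six grades aggregate by mean-min into `eta_dv`.
#'
#' @param perturbed an `ft_flux_state` of the perturbed normal model.
#' @param templates an `ft_templates`.
#' @param perturbed_flow optional precomputed [metabolite_flow()] of
#'   `perturbed` (computed on the normal model when omitted).
#' @param bl the normal model (only needed when `perturbed_flow` is NULL).
#' @param eps floor of the deviation scale, guarding reactions where the two
#'   templates coincide.
#' @return list with `eta_sf`, `eta_sm`, `eta_lf`, `eta_lm`, `eta_v`,
#'   `eta_m`, `eta_dv`.
#' @export
grade_deviation <- function(perturbed, templates, perturbed_flow = NULL,
                            bl = NULL, eps = 1e-6) {
  stopifnot(inherits(templates, "ft_templates"))
  if (is.null(perturbed_flow)) {
    if (is.null(bl)) stop("need bl model or a precomputed perturbed_flow",
                          call. = FALSE)
    perturbed_flow <- metabolite_flow(perturbed, bl)
  }
  v_pb_all <- net_flux(perturbed)
  v_ca_all <- net_flux(templates$ca)
  v_bl_all <- net_flux(templates$bl)
  bl_internal <- templates$bl_split$rxn_ids[templates$bl_split$internal]
  rxns <- intersect(intersect(bl_internal, names(v_ca_all)), names(v_pb_all))
  if (!length(rxns)) stop("no shared internal reactions to grade", call. = FALSE)
  v_pb <- v_pb_all[rxns]; v_ca <- v_ca_all[rxns]; v_bl <- v_bl_all[rxns]

  sp <- intersect(intersect(names(templates$bl_flow), names(templates$ca_flow)),
                  names(perturbed_flow))
  r_pb <- perturbed_flow[sp]; r_ca <- templates$ca_flow[sp]
  r_bl <- templates$bl_flow[sp]

  if (eps == 0 && all(abs(v_ca - v_bl) == 0) && all(abs(r_ca - r_bl) == 0)) {
    stop("degenerate deviation scales: cancer and normal templates coincide",
         call. = FALSE)
  }
  part_grades <- function(pb, ca, bl_) {
    tau <- eps * pmax(1, abs(bl_))
    d <- pmax(abs(ca - bl_), tau)
    mu_dis <- clip01(abs(pb - ca) / d)
    mu_sim <- 1 - clip01(abs(pb - bl_) / d)
    # partition on template differences beyond numerical noise
    s_set <- ca < bl_ - tau
    l_set <- ca > bl_ + tau
    list(
      smaller = if (any(s_set)) mean(mu_dis[s_set]) else 1,
      larger = if (any(l_set)) mean(mu_dis[l_set]) else 1,
      sim = mean(mu_sim)
    )
  }
  gv <- part_grades(v_pb, v_ca, v_bl)
  gm <- part_grades(r_pb, r_ca, r_bl)
  out <- list(eta_sf = gv$smaller, eta_sm = gm$smaller,
              eta_lf = gv$larger, eta_lm = gm$larger,
              eta_v = gv$sim, eta_m = gm$sim)
  out$eta_dv <- mean_min(out$eta_sf, out$eta_sm, out$eta_lf, out$eta_lm,
                         out$eta_v, out$eta_m)
  out
}

#' Side-effect grade
#'
#' Mean-min of the perturbed-cell viability grade and the metabolic
#' deviation grade. Higher means fewer predicted side effects.
#'
#' @param eta_cvpb,eta_dv grades in \[0, 1\].
#' @return `eta_se`.
#' @export
grade_side_effect <- function(eta_cvpb, eta_dv) {
  mean_min(eta_cvpb, eta_dv)
}

#' Top of the grade hierarchy
#'
#' `eta_cv = mean_min(eta_cvtr, eta_cvpb)` combines treated-cancer mortality
#' with perturbed-normal viability; the overall fitness is
#' `eta_d = (eta_cv + min(eta_cv, eta_dv)) / 2`.
#'
#' @param eta_cvtr,eta_cvpb,eta_dv grades in \[0, 1\].
#' @return list with `eta_cv` and `eta_d`.
#' @export
grade_hierarchy <- function(eta_cvtr, eta_cvpb, eta_dv) {
  eta_cv <- mean_min(eta_cvtr, eta_cvpb)
  list(eta_cv = eta_cv, eta_d = (eta_cv + min(eta_cv, eta_dv)) / 2)
}

#' Invert the cell-viability aggregation
#'
#' Recovers `eta_cvpb` from a reported combined grade `eta_cv` given
#' `eta_cvtr` (1 for any treatment that killed the cancer model). Under the
#' mean-min rule, `eta_cv = (eta_cvtr + 3 eta_cvpb) / 4` when
#' `eta_cvpb <= eta_cvtr`, hence `eta_cvpb = (4 eta_cv - eta_cvtr) / 3`;
#' the complementary branch is used when that root exceeds `eta_cvtr`.
#'
#' @param eta_cv combined cell-viability grade.
#' @param eta_cvtr treated-cancer mortality grade (default 1).
#' @return `eta_cvpb` in \[0, 1\].
#' @export
invert_eta_cv <- function(eta_cv, eta_cvtr = 1) {
  b <- (4 * eta_cv - eta_cvtr) / 3
  if (b > eta_cvtr) b <- 4 * eta_cv - 3 * eta_cvtr
  if (b < -1e-9 || b > 1 + 1e-9) {
    stop("inverted eta_cvpb = ", signif(b, 6), " falls outside [0, 1]",
         call. = FALSE)
  }
  clip01(b)
}

#' Assemble a full grade set
#'
#' @param eta_cvtr mortality grade.
#' @param viability list from [grade_perturbed_viability()].
#' @param deviation list from [grade_deviation()].
#' @return an `ft_grades` list with all fourteen grades.
#' @export
grade_set <- function(eta_cvtr, viability, deviation) {
  h <- grade_hierarchy(eta_cvtr, viability$eta_cvpb, deviation$eta_dv)
  structure(c(
    list(eta_cvtr = eta_cvtr),
    viability[c("eta_biomass_pb", "eta_atp_pb", "eta_cvpb")],
    list(eta_cv = h$eta_cv),
    deviation[c("eta_sf", "eta_sm", "eta_lf", "eta_lm", "eta_v", "eta_m",
                "eta_dv")],
    list(eta_se = grade_side_effect(viability$eta_cvpb, deviation$eta_dv),
         eta_d = h$eta_d)
  ), class = "ft_grades")
}

#' @export
print.ft_grades <- function(x, ...) {
  v <- unlist(x)
  cat("<ft_grades>\n")
  print(round(v, 3))
  invisible(x)
}

#' @export
as.data.frame.ft_grades <- function(x, ...) {
  as.data.frame(lapply(unclass(x), identity))
}
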