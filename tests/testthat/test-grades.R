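test_that("linear membership hits its anchors and midpoint", {
  up <- membership_spec(0, 10, "maximize")
  dn <- membership_spec(0, 10, "minimize")
  expect_equal(linear_membership(10, up), 1)
  expect_equal(linear_membership(0, up), 0)
  expect_equal(linear_membership(5, up), 0.5)
  expect_equal(linear_membership(5, dn), 0.5)
  expect_equal(linear_membership(-3, up), 0)   # clipped
  expect_equal(linear_membership(42, up), 1)
  expect_error(membership_spec(1, 1), "x0 < x1")
})

test_that("mean-min reproduces the published aggregation values", {
  # frozen worked examples from the reported colorectal study grades
  expect_equal(mean_min(1.0, 0.625), 0.71875)
  expect_equal(mean_min(0.625, 0.675), 0.6375)
  expect_equal(grade_side_effect(0.625, 0.448), 0.49225)
  expect_equal(grade_side_effect(1.0, 0.303), 0.47725)
  expect_error(mean_min(numeric(0)), "at least one")
  expect_error(mean_min(1.2), "\\[0, 1\\]")
})

test_that("mean-min is idempotent and squeezed between min and mean", {
  set.seed(11)
  for (i in 1:50) {
    g <- runif(sample(2:6, 1))
    mm <- mean_min(g)
    expect_gte(mm, min(g))
    expect_lte(mm, mean(g))
    if (diff(range(g)) > 0) expect_lt(mm, mean(g))
  }
  for (a in c(0, 0.3, 1)) expect_equal(mean_min(rep(a, 4)), a)
})

test_that("mortality grading anchors at no-effect and death", {
  expect_equal(grade_mortality(0, 10), 1)
  expect_equal(grade_mortality(1e-11, 10), 1)  # at the death threshold
  expect_equal(grade_mortality(10, 10), 0)
  expect_equal(grade_mortality(5, 10), 0.5)
  expect_error(grade_mortality(1, 0), "positive")
})

test_that("perturbed-viability grades follow the mean-min identities", {
  fake <- function(atp, biomass) {
    structure(list(atp = atp, biomass = biomass), class = "ft_flux_state")
  }
  v <- grade_perturbed_viability(fake(62.5, 0), 100, 10)
  expect_equal(v$eta_atp_pb, 0.625)
  expect_equal(v$eta_biomass_pb, 1)
  expect_equal(v$eta_cvpb, mean_min(1, 0.625))
  # equal inputs collapse to themselves
  v2 <- grade_perturbed_viability(fake(62.5, 3.75), 100, 10)
  expect_equal(v2$eta_cvpb, 0.625)
  # an infeasible (all-zero) perturbed model caps the viability at 0.25
  v3 <- grade_perturbed_viability(fake(0, 0), 100, 10)
  expect_equal(v3$eta_atp_pb, 0)
  expect_lte(v3$eta_cvpb, 0.25)
})

test_that("hierarchy and side-effect grades compose as specified", {
  h <- grade_hierarchy(1.0, 0.625, 0.675)
  expect_equal(h$eta_cv, 0.71875)
  expect_equal(h$eta_d, (0.71875 + 0.675) / 2)
  expect_equal(grade_hierarchy(1, 1, 1)$eta_d, 1)
  # eta_dv above eta_cv does not lift the fitness past eta_cv
  expect_equal(grade_hierarchy(1, 1, 0.4)$eta_d, 0.7)
})

test_that("inverting the viability aggregation recovers the perturbed grade", {
  expect_equal(invert_eta_cv(0.719), (4 * 0.719 - 1) / 3)
  expect_equal(invert_eta_cv(1), 1)
  expect_equal(invert_eta_cv(0.953), 0.93733, tolerance = 1e-4)
  set.seed(21)
  for (cvpb in runif(25)) {
    cv <- mean_min(1, cvpb)
    expect_equal(invert_eta_cv(cv), cvpb, tolerance = 1e-12)
  }
  expect_error(invert_eta_cv(0.1), "outside")
})

test_that("deviation grades anchor at the two templates", {
  toy <- toy_cached()
  tpl <- toy$templates
  # perturbed == normal template: perfect similarity, full dissimilarity
  d_bl <- grade_deviation(tpl$bl, tpl, perturbed_flow = tpl$bl_flow)
  expect_equal(d_bl$eta_v, 1)
  expect_equal(d_bl$eta_m, 1)
  expect_equal(d_bl$eta_sf, 1)
  expect_equal(d_bl$eta_lf, 1)
  expect_equal(d_bl$eta_dv, 1)
  # perturbed == cancer template: dissimilarity collapses
  ca_as_bl <- tpl$ca
  d_ca <- grade_deviation(ca_as_bl, tpl, perturbed_flow = tpl$ca_flow)
  expect_equal(d_ca$eta_sf, 0, tolerance = 1e-6)
  expect_equal(d_ca$eta_lf, 0, tolerance = 1e-6)
  expect_lt(d_ca$eta_dv, d_bl$eta_dv)
})

test_that("moving from the cancer to the normal template raises similarity", {
  toy <- toy_cached()
  tpl <- toy$templates
  blend <- function(alpha) {
    st <- tpl$ca
    st$vf <- (1 - alpha) * tpl$ca$vf + alpha * tpl$bl$vf
    st$vb <- (1 - alpha) * tpl$ca$vb + alpha * tpl$bl$vb
    flow <- (1 - alpha) * tpl$ca_flow + alpha * tpl$bl_flow
    grade_deviation(st, tpl, perturbed_flow = flow)
  }
  etas <- vapply(seq(0, 1, by = 0.1), function(a) blend(a)$eta_v, numeric(1))
  expect_true(all(diff(etas) >= -1e-9))
  # at the cancer end, similarity is lost exactly on the reactions where the
  # two templates genuinely differ
  expect_lt(etas[1], etas[11])
  expect_equal(etas[11], 1)
})

test_that("grade pipeline is invariant to uniform flux rescaling", {
  toy <- toy_cached()
  tpl <- toy$templates
  scale_state <- function(st, s) { st$vf <- st$vf * s; st$vb <- st$vb * s; st }
  tpl2 <- tpl
  s <- 3.7
  tpl2$ca <- scale_state(tpl$ca, s)
  tpl2$bl <- scale_state(tpl$bl, s)
  tpl2$ca_flow <- tpl$ca_flow * s
  tpl2$bl_flow <- tpl$bl_flow * s
  pb <- scale_state(tpl$ca, s)
  d1 <- grade_deviation(tpl$ca, tpl, perturbed_flow = tpl$ca_flow)
  d2 <- grade_deviation(pb, tpl2, perturbed_flow = tpl$ca_flow * s)
  expect_equal(d1$eta_dv, d2$eta_dv, tolerance = 1e-6)
})

test_that("full grade sets stay inside the unit interval", {
  toy <- toy_cached()
  set.seed(5)
  pool <- candidate_pools(lapply(toy$pair$bl$genes, function(g)
    target("gene", g)))
  for (g in toy$pair$bl$genes[1:5]) {
    gr <- evaluate_treatment(treatment_set(target("gene", g)),
                             toy$pair$ca, toy$pair$bl, toy$templates)
    vals <- unlist(gr)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(gr$eta_cv, mean_min(gr$eta_cvtr, gr$eta_cvpb))
    expect_equal(gr$eta_se, mean_min(gr$eta_cvpb, gr$eta_dv))
    expect_equal(gr$eta_d, (gr$eta_cv + min(gr$eta_cv, gr$eta_dv)) / 2)
  }
})
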