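test_that("FBA routes a single-path chain at full capacity", {
  m <- chain_model(cap = 10)
  sp <- split_reversible(m)
  st <- solve_fba(sp, objective_weights(0, 1))
  expect_identical(st$status, "optimal")
  expect_equal(st$biomass, 10, tolerance = 1e-9)
  # sole pathway knocked to [0, 0]: dead with zero growth
  r <- reaction_to_restrictions(m, "TRANS", "inhibit", 0)
  st0 <- solve_fba(sp, objective_weights(0, 1), r)
  expect_identical(st0$status, "dead")
  expect_equal(st0$biomass, 0)
})

test_that("splitting leaves the linear optimum unchanged", {
  # oracle: net-flux formulation solved by an unrelated algorithm
  toy <- toy_cached()$pair
  for (m in list(toy$ca, toy$bl)) {
    direct <- fluxtarget:::toy_fba(m, m$biomass_id)
    split <- solve_fba(split_reversible(m), objective_weights(0, 1))
    expect_equal(split$biomass, direct, tolerance = 1e-5)
  }
})

test_that("flux minimization splits symmetric parallel paths evenly", {
  m <- parallel_model(demand = 8)
  sp <- split_reversible(m)
  fba <- solve_fba(sp, objective_weights(0, 1))
  ufd <- solve_ufd(sp, NULL, objective_weights(0, 1), fba$objective_value)
  v <- net_flux(ufd)
  # analytic: min x^2 + (T - x)^2 at x = T/2
  expect_equal(unname(v["P1"]), 4, tolerance = 1e-6)
  expect_equal(unname(v["P2"]), 4, tolerance = 1e-6)
  expect_gte(ufd$objective_value, fba$objective_value * (1 - 1e-5))
})

test_that("flux minimization is a no-op on a single-path model", {
  m <- chain_model(cap = 6)
  sp <- split_reversible(m)
  fba <- solve_fba(sp, objective_weights(0, 1))
  ufd <- solve_ufd(sp, NULL, objective_weights(0, 1), fba$objective_value)
  expect_equal(net_flux(ufd), net_flux(fba), tolerance = 1e-5)
})

test_that("internal fluxes at the minimum are unique across solver orderings", {
  toy <- toy_cached()
  m <- toy$pair$bl
  perm <- rev(seq_len(nrow(m$reactions)))
  m2 <- ft_model(m$metabolites, m$reactions[perm, ],
                 m$stoich[, perm, drop = FALSE], m$genes,
                 m$biomass_id, m$atp_id, m$label)
  solve_pair <- function(model) {
    sp <- split_reversible(model)
    fba <- solve_fba(sp, objective_weights(1, 1))
    solve_ufd(sp, NULL, objective_weights(1, 1), fba$objective_value)
  }
  v1 <- net_flux(solve_pair(m))
  v2 <- net_flux(solve_pair(m2))
  ids <- internal_reactions(m)
  expect_equal(v1[ids], v2[ids], tolerance = 1e-6)
})

test_that("tightening restrictions never raises the optimum", {
  toy <- toy_cached()
  sp <- toy$templates$ca_split
  base <- solve_fba(sp, objective_weights(0, 1))$objective_value
  for (s in c(0.75, 0.5, 0.25, 0)) {
    r <- reaction_to_restrictions(toy$pair$ca, "GLY", "inhibit", s)
    val <- solve_fba(sp, objective_weights(0, 1), r)$objective_value
    expect_lte(val, base + 1e-9)
    base <- val
  }
})

test_that("optimal states satisfy steady state and the quadratic bound", {
  toy <- toy_cached()
  for (mdl in list(toy$pair$ca, toy$pair$bl)) {
    sp <- split_reversible(mdl)
    fba <- solve_fba(sp, objective_weights(0, 1))
    ufd <- solve_ufd(sp, NULL, objective_weights(0, 1), fba$objective_value)
    expect_lte(steady_state_residual(fba, sp), 1e-6)
    expect_lte(steady_state_residual(ufd, sp), 1e-6)
    internal <- sp$internal
    fba_q <- sum(fba$vf[internal]^2 + fba$vb[internal]^2)
    expect_lte(ufd$quadratic, fba_q + 1e-6)
  }
})

test_that("an emptied polytope reports infeasible with zero fluxes", {
  m <- chain_model()
  m$reactions$lower_bound[m$reactions$id == "BIOMASS"] <- 50  # demand > supply
  st <- solve_fba(split_reversible(m), objective_weights(0, 1))
  expect_identical(st$status, "infeasible")
  expect_true(all(st$vf == 0) && all(st$vb == 0))
})

test_that("templates are deterministic across repeated computation", {
  toy <- toy_cached()
  t2 <- compute_templates(toy$pair$ca, toy$pair$bl)
  expect_equal(net_flux(toy$templates$ca), net_flux(t2$ca))
  expect_equal(net_flux(toy$templates$bl), net_flux(t2$bl))
  expect_equal(toy$templates$bl_flow, t2$bl_flow)
})
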