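gene_pool <- function(model) {
  candidate_pools(lapply(model$genes, function(g) target("gene", g)))
}

test_that("planted targets get the expected mortality grades", {
  toy <- toy_cached()
  lethal <- evaluate_treatment(treatment_set(target("gene", "g_lethal")),
                               toy$pair$ca, toy$pair$bl, toy$templates)
  expect_equal(lethal$eta_cvtr, 1)
  safe <- evaluate_treatment(treatment_set(target("gene", "g_safe")),
                             toy$pair$ca, toy$pair$bl, toy$templates)
  expect_equal(safe$eta_cvtr, 0)
})

test_that("fitness evaluations are memoized by canonical target set", {
  toy <- toy_cached()
  cache <- new.env(parent = emptyenv())
  tr_a <- treatment_set(target("gene", "g_gly"), target("gene", "g_oxp"))
  tr_b <- treatment_set(target("gene", "g_oxp"), target("gene", "g_gly"))
  g1 <- evaluate_treatment(tr_a, toy$pair$ca, toy$pair$bl, toy$templates, cache)
  g2 <- evaluate_treatment(tr_b, toy$pair$ca, toy$pair$bl, toy$templates, cache)
  expect_equal(cache$.misses, 1L)   # order-insensitive key: one real solve
  expect_equal(cache$.hits, 1L)
  expect_equal(unclass(g1)[], unclass(g2)[])
})

test_that("exhaustive enumeration has the right combinatorics", {
  toy <- toy_cached()
  six <- candidate_pools(lapply(toy$pair$bl$genes[1:6], function(g)
    target("gene", g)))
  r2 <- exhaustive_search(toy$pair$ca, toy$pair$bl, six, K = 2,
                          templates = toy$templates)
  expect_equal(nrow(r2), choose(6, 2))
  one <- candidate_pools(list(target("gene", "g_lethal")))
  r1 <- exhaustive_search(toy$pair$ca, toy$pair$bl, one, K = 1,
                          templates = toy$templates)
  expect_equal(nrow(r1), 1)
  expect_match(r1$treatment[1], "g_lethal")
  big <- candidate_pools(lapply(sprintf("g%03d", 1:120), function(g)
    target("gene", g)))
  expect_error(exhaustive_search(toy$pair$ca, toy$pair$bl, big, K = 2,
                                 templates = toy$templates), "guard")
})

test_that("the search is reproducible and recovers the planted optimum", {
  toy <- toy_cached()
  pool <- gene_pool(toy$pair$bl)
  cfg <- nhde_config(generations = 15, seed = 9)
  r1 <- run_search(toy$pair$ca, toy$pair$bl, pool, K = 1, config = cfg,
                   templates = toy$templates)
  r2 <- run_search(toy$pair$ca, toy$pair$bl, pool, K = 1, config = cfg,
                   templates = toy$templates)
  expect_identical(r1, r2)
  expect_match(r1$treatment[1], "g_lethal")
  # the exhaustive oracle can never be beaten
  ex <- exhaustive_search(toy$pair$ca, toy$pair$bl, pool, K = 1,
                          templates = toy$templates)
  expect_gte(ex$eta_d[1], r1$eta_d[1] - 1e-12)
})

test_that("two-group pooling puts a group-one member in every combination", {
  toy <- toy_cached()
  pools <- candidate_pools(
    list(target("gene", "g_lethal"), target("gene", "g_safe")),
    lapply(c("g_gly", "g_oxp", "g_lac"), function(g) target("gene", g)))
  ex <- exhaustive_search(toy$pair$ca, toy$pair$bl, pools, K = 2,
                          templates = toy$templates)
  expect_equal(nrow(ex), 2 * 3)
  expect_true(all(grepl("g_lethal|g_safe", ex$treatment)))
  rs <- run_search(toy$pair$ca, toy$pair$bl, pools, K = 2,
                   config = nhde_config(generations = 10, seed = 2),
                   templates = toy$templates)
  first_member <- vapply(attr(rs, "treatments"), function(tr)
    any(vapply(tr$targets, function(t) t$id %in% c("g_lethal", "g_safe"),
               logical(1))), logical(1))
  expect_true(all(first_member))
})

test_that("duplicate indices are repaired into valid target sets", {
  toy <- toy_cached()
  pool <- gene_pool(toy$pair$bl)
  sp <- fluxtarget:::slot_pools(pool, 2)
  set.seed(4)
  for (i in 1:20) {
    z <- fluxtarget:::repair_z(c(3L, 3L), sp)
    keys <- fluxtarget:::target_keys(lapply(seq_along(z), function(s)
      sp[[s]][[z[s]]]))
    expect_false(anyDuplicated(keys) > 0)
  }
})
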