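test_that("metabolite flow sums production over compartments and directions", {
  m <- chain_model()
  sp <- split_reversible(m)
  st <- solve_fba(sp, objective_weights(0, 1))
  fl <- metabolite_flow(st, m)
  # base species 'a' pools a_e and a_c: produced by SRC (10) and TRANS (10)
  expect_equal(unname(fl["a"]), 20, tolerance = 1e-8)
  # all-zero state maps to all-zero flows
  zero <- st
  zero$vf[] <- 0
  zero$vb[] <- 0
  expect_true(all(metabolite_flow(zero, m) == 0))
})

test_that("a reverse-running consumer counts as a producer", {
  mets <- data.frame(id = c("a_c", "b_c"))
  rxns <- data.frame(id = c("SRC_b", "CONV", "DM_a"),
                     lower_bound = c(0, -10, 0), upper_bound = c(5, 10, 10),
                     gpr = "", stringsAsFactors = FALSE)
  S <- matrix(0, 2, 3, dimnames = list(mets$id, rxns$id))
  S["b_c", "SRC_b"] <- 1
  S["a_c", "CONV"] <- -1   # forward: a -> b; backward run makes a
  S["b_c", "CONV"] <- 1
  S["a_c", "DM_a"] <- -1
  m <- ft_model(mets, rxns, S, biomass_id = "DM_a", atp_id = "DM_a")
  sp <- split_reversible(m)
  st <- solve_fba(sp, objective_weights(0, 1))  # maximize a demand
  expect_equal(st$biomass, 5, tolerance = 1e-8)
  fl <- metabolite_flow(st, m)
  expect_equal(unname(fl["a"]), 5, tolerance = 1e-8)  # made via CONV backwards
})

test_that("production equals consumption for non-exchanged species", {
  toy <- toy_cached()
  for (entry in list(list(toy$templates$ca, toy$pair$ca),
                     list(toy$templates$bl, toy$pair$bl))) {
    st <- entry[[1]]; m <- entry[[2]]
    prod <- metabolite_flow(st, m)
    cons <- fluxtarget:::metabolite_consumption(st, m)
    exch_rows <- Matrix::rowSums(m$stoich[, is_exchange(m), drop = FALSE] != 0) > 0
    closed <- setdiff(unique(m$metabolites$base_species),
                      m$metabolites$base_species[exch_rows])
    expect_gt(length(closed), 0)
    expect_equal(prod[closed], cons[closed], tolerance = 1e-6)
  }
})

test_that("flows are invariant to splitting a reaction into half-flux copies", {
  m <- parallel_model(demand = 8)    # P1/P2 are identical copies
  sp <- split_reversible(m)
  fba <- solve_fba(sp, objective_weights(0, 1))
  ufd <- solve_ufd(sp, NULL, objective_weights(0, 1), fba$objective_value)
  merged <- chain_like <- m
  # collapse P2 into P1 by rerouting all flux through one path
  one <- ufd
  one$vf[match("P1", sp$rxn_ids)] <- sum(ufd$vf[match(c("P1", "P2"), sp$rxn_ids)])
  one$vf[match("P2", sp$rxn_ids)] <- 0
  expect_equal(metabolite_flow(ufd, m), metabolite_flow(one, m),
               tolerance = 1e-9)
})

test_that("fold changes anchor at identity, doubling, and drop unchanged rows", {
  bl <- c(a = 4, b = 8, c = 0)
  expect_equal(unname(log2_fold_changes(list(p = bl), bl, drop_tol = 0)["a", 1]), 0)
  dbl <- c(a = 8, b = 8, c = 0)
  L <- log2_fold_changes(list(p = dbl), bl)
  expect_equal(unname(L["a", 1]), 1, tolerance = 1e-6)
  expect_false("b" %in% rownames(L))   # unchanged row dropped
  expect_false("c" %in% rownames(L))   # 0/0 with pseudo-flow is unchanged
  # normal state against itself is empty after filtering
  expect_equal(nrow(log2_fold_changes(list(p = bl), bl)), 0)
  expect_error(log2_fold_changes(list(p = c(a = -1, b = 1, c = 1)), bl),
               "negative")
  expect_error(log2_fold_changes(list(p = c(x = 1)), bl), "species support")
})

test_that("a rank-one pattern is captured by a single dominant factor", {
  set.seed(31)
  u <- rnorm(30)
  w <- rnorm(8)
  X <- outer(u, w) + matrix(rnorm(240, sd = 0.05), 30, 8)
  fa <- factor_analysis(X, 2)
  expect_gte(fa$prop_common[1], 0.95)
  expect_lte(sum(fa$prop_var), 1)
})

test_that("orthogonal block patterns separate onto their own factors", {
  set.seed(32)
  n_obs <- 12
  f1 <- rnorm(n_obs); f2 <- rnorm(n_obs)
  X <- rbind(outer(rep(1, 15), f1), outer(rep(1, 15), f2)) +
    matrix(rnorm(30 * n_obs, sd = 0.05), 30, n_obs)
  fa <- factor_analysis(X, 2)
  L <- abs(fa$loadings)
  block <- rep(1:2, each = 15)
  dominant <- max.col(L)
  # each block loads coherently on one factor, and the two blocks differ
  expect_true(all(tapply(dominant, block, function(d) length(unique(d))) == 1))
  expect_equal(length(unique(tapply(dominant, block, unique))), 2)
  expect_gte(min(tapply(apply(L, 1, max), block, min)), 0.9)
})

test_that("quartimax rotation preserves communalities", {
  set.seed(33)
  L <- matrix(rnorm(40), 10, 4)
  R <- fluxtarget:::quartimax_rotate(L)
  expect_equal(rowSums(R^2), rowSums(L^2), tolerance = 1e-6)
  # and it never decreases the quartimax criterion
  expect_gte(sum(R^4), sum(L^4) - 1e-9)
})

test_that("factor analysis rejects malformed inputs", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(factor_analysis(X, 5), "columns")
  X[1, 1] <- NA
  expect_error(factor_analysis(X, 2), "missing")
})
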