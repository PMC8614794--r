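test_that("gene knockouts propagate through GPRs with isozyme rescue", {
  toy <- toy_cached()$pair
  # single association: GLY carries g_gly alone
  r <- gene_to_restrictions(toy$ca, "g_gly", strength = 0)
  expect_setequal(r$bounds$rxn_id, "GLY")
  expect_true(all(r$bounds$ub == 0))
  # partial repression keeps a fraction of the bound
  r5 <- gene_to_restrictions(toy$ca, "g_gly", strength = 0.5)
  expect_equal(max(r5$bounds$ub), 0.5 * 100)
  expect_error(gene_to_restrictions(toy$ca, "not_a_gene"), "unknown gene")
})

test_that("an OR rule survives a single knockout but not a joint one", {
  mets <- data.frame(id = "a_c")
  rxns <- data.frame(id = c("SRC", "USE"), lower_bound = 0,
                     upper_bound = c(5, 5), gpr = c("", "g1 or g2"),
                     stringsAsFactors = FALSE)
  S <- matrix(c(1, -1), 1, 2, dimnames = list("a_c", c("SRC", "USE")))
  m <- ft_model(mets, rxns, S, biomass_id = "USE", atp_id = "USE")
  expect_equal(nrow(gene_to_restrictions(m, "g1")$bounds), 0)
  joint <- gene_to_restrictions(m, c("g1", "g2"))
  expect_setequal(joint$bounds$rxn_id, "USE")
})

test_that("gene- and reaction-centric routes agree for one-to-one pairs", {
  toy <- toy_cached()$pair
  rg <- gene_to_restrictions(toy$ca, "g_lethal", 0)
  rr <- reaction_to_restrictions(toy$ca, "CAP", "inhibit", 0)
  o <- function(b) b[order(b$rxn_id, b$dir), ]
  expect_equal(o(rg$bounds), o(rr$bounds), ignore_attr = TRUE)
})

test_that("antimetabolite inhibition blocks producers and spares consumers", {
  toy <- toy_cached()$pair
  # caprec is made by exactly one irreversible reaction
  r <- metabolite_to_restrictions(toy$ca, "caprec", "inhibit", 0)
  expect_equal(r$bounds$rxn_id, "CAP")
  expect_equal(r$bounds$dir, "f")
  expect_equal(r$bounds$ub, 0)
  # prec has two producing reactions; both blocked, the consumer untouched
  r2 <- metabolite_to_restrictions(toy$ca, "prec", "inhibit", 0)
  expect_setequal(r2$bounds$rxn_id, c("PREC1", "PREC2"))
  expect_false("BIOMASS" %in% r2$bounds$rxn_id)
  expect_error(metabolite_to_restrictions(toy$ca, "nope", "inhibit", 0),
               "unknown base species")
  # a species made only by a boundary reaction has no internal producer
  mets <- data.frame(id = "x_c")
  rxns <- data.frame(id = c("SRC", "DM"), lower_bound = 0, upper_bound = 5,
                     gpr = "", stringsAsFactors = FALSE)
  S <- matrix(c(1, -1), 1, 2, dimnames = list("x_c", c("SRC", "DM")))
  m <- ft_model(mets, rxns, S, biomass_id = "DM", atp_id = "DM")
  expect_error(metabolite_to_restrictions(m, "x", "inhibit", 0),
               "not produced")
})

test_that("enhancement at factor one leaves the normal template unchanged", {
  toy <- toy_cached()
  ref <- unname(toy$templates$bl_flow["atp"])
  r <- metabolite_to_restrictions(toy$pair$bl, "atp", "enhance", 1,
                                  reference_flow = ref)
  st <- solve_fba(toy$templates$bl_split, objective_weights(1, 1), r)
  expect_equal(st$objective_value, toy$templates$bl_fba$objective_value,
               tolerance = 1e-6)
  ufd <- solve_ufd(toy$templates$bl_split, r, objective_weights(1, 1),
                   st$objective_value)
  expect_equal(net_flux(ufd), net_flux(toy$templates$bl), tolerance = 1e-5)
})

test_that("applying restrictions intersects intervals and copies the model", {
  toy <- toy_cached()
  sp <- toy$templates$ca_split
  # empty set: unchanged
  sp0 <- apply_restrictions(sp, restriction_set())
  expect_equal(sp0$vf_ub, sp$vf_ub)
  # two restrictions on one slot: intersection
  r <- restriction_set(bounds = data.frame(
    rxn_id = c("GLY", "GLY"), dir = "f", lb = c(0, 2), ub = c(7, 50)))
  sp2 <- apply_restrictions(sp, r)
  j <- match("GLY", sp2$rxn_ids)
  expect_equal(c(sp2$vf_lb[j], sp2$vf_ub[j]), c(2, 7))
  # original untouched
  expect_equal(sp$vf_lb[j], 0)
  # a knockout restriction forces zero flux at that slot
  rko <- reaction_to_restrictions(toy$pair$ca, "LACS", "inhibit", 0)
  st <- solve_fba(sp, objective_weights(0, 1), rko)
  expect_equal(unname(net_flux(st)["LACS"]), 0)
})

test_that("inhibit-mode targets never enlarge the feasible optimum", {
  toy <- toy_cached()
  base <- solve_fba(toy$templates$ca_split,
                    objective_weights(0, 1))$objective_value
  for (t in list(target("gene", "g_oxp"), target("reaction", "GLY"),
                 target("metabolite", "pyr"))) {
    r <- treatment_restrictions(toy$pair$ca, treatment_set(t), toy$templates)
    val <- solve_fba(toy$templates$ca_split, objective_weights(0, 1),
                     r)$objective_value
    expect_lte(val, base + 1e-9)
  }
})

test_that("treatment sets validate cardinality and duplicates", {
  expect_error(treatment_set(), "between one and three")
  expect_error(treatment_set(target("gene", "a"), target("gene", "a")),
               "duplicate")
  t4 <- lapply(letters[1:4], function(x) target("gene", x))
  expect_error(treatment_set(t4), "between one and three")
  expect_error(target("gene", "a", "enhance"), "enhance mode")
  tr <- parse_target("met:fol:enhance:1.5")
  expect_equal(tr$kind, "metabolite")
  expect_equal(tr$strength, 1.5)
})
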