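# Shared fixtures: the default toy pair (with templates) is expensive enough
# to build once per test run, and a couple of hand-sized models exercise the
# solvers against closed-form answers.

toy_cached <- local({
  store <- new.env(parent = emptyenv())
  function() {
    if (is.null(store$pair)) {
      store$pair <- make_toy_pair(toy_config())
      store$templates <- compute_templates(store$pair$ca, store$pair$bl)
    }
    list(pair = store$pair, templates = store$templates)
  }
})

# linear chain: uptake (<= cap) -> A -> biomass, yield 1; trivial single path
chain_model <- function(cap = 10) {
  mets <- data.frame(id = c("a_e", "a_c"))
  rxns <- data.frame(
    id = c("SRC", "TRANS", "BIOMASS", "DM_atp"),
    lower_bound = c(0, 0, 0, 0),
    upper_bound = c(cap, 100, 100, 100),
    gpr = c("", "g1", "", ""),
    stringsAsFactors = FALSE
  )
  S <- matrix(0, 2, 4, dimnames = list(mets$id, rxns$id))
  S["a_e", "SRC"] <- 1
  S["a_e", "TRANS"] <- -1
  S["a_c", "TRANS"] <- 1
  S["a_c", "BIOMASS"] <- -1
  S["a_c", "DM_atp"] <- -1
  ft_model(mets, rxns, S, biomass_id = "BIOMASS", atp_id = "DM_atp",
           label = "BL")
}

# two identical parallel internal paths carrying a demanded flux: the
# flux-minimization stage must split the demand evenly
parallel_model <- function(demand = 8) {
  mets <- data.frame(id = c("a_c", "b_c"))
  rxns <- data.frame(
    id = c("SRC", "P1", "P2", "BIOMASS", "DM_atp"),
    lower_bound = c(demand, 0, 0, 0, 0),
    upper_bound = c(demand, 100, 100, 100, 100),
    gpr = "",
    stringsAsFactors = FALSE
  )
  S <- matrix(0, 2, 5, dimnames = list(mets$id, rxns$id))
  S["a_c", "SRC"] <- 1
  S["a_c", c("P1", "P2")] <- -1
  S["b_c", c("P1", "P2")] <- 1
  S["b_c", "BIOMASS"] <- -1
  S["a_c", "DM_atp"] <- 0
  S["b_c", "DM_atp"] <- -1
  ft_model(mets, rxns, S, biomass_id = "BIOMASS", atp_id = "DM_atp",
           label = "BL")
}

steady_state_residual <- function(state, split) {
  N <- stoichiometric_matrix(split)
  max(abs(as.numeric(N %*% c(state$vf, state$vb))))
}
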