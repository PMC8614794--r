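#' Published reference grades for colorectal-cancer target predictions
#'
#' Reported membership-grade triples (cell viability `eta_cv`, metabolic
#' deviation `eta_dv`, side effect `eta_se`) for the top twenty one-target
#' gene interventions and the top ten one-target antimetabolites in a
#' colorectal cancer / normal model pair. Every reported treatment killed
#' the cancer model, so `eta_cvtr = 1` throughout and the rows double as a
#' regression fixture for the mean-min aggregation identities:
#' `eta_se` should equal
#' `mean_min(invert_eta_cv(eta_cv), eta_dv)` to the printed precision.
#'
#' @param approach `"gene"`, `"metabolite"` or `"all"` (default).
#' @return data.frame with columns `target`, `kind`, `eta_cv`, `eta_dv`,
#'   `eta_se`.
#' @export
reference_grades <- function(approach = c("all", "gene", "metabolite")) {
  approach <- match.arg(approach)
  gene <- data.frame(
    target = c("HMGCR", "MVK", "MVD", "PMVK", "SQLE", "FDFT1", "EBP", "LSS",
               "NSDHL", "SPTLC1/2/3", "KDSR", "CRLS1", "PGS1", "PTDSS1",
               "ADSL", "ADSS2", "UMPS", "DHODH", "CAD", "RPIA"),
    kind = "gene",
    eta_cv = c(0.719, 0.719, 0.719, 0.719, 0.719, 0.719, 0.719, 0.719,
               0.719, 0.719, 0.719, 0.719, 0.719, 1.0,
               0.719, 0.719, 0.719, 0.719, 0.719, 0.719),
    eta_dv = c(0.675, 0.669, 0.669, 0.669, 0.672, 0.674, 0.674, 0.672,
               0.674, 0.670, 0.670, 0.669, 0.448, 0.303,
               0.669, 0.669, 0.655, 0.448, 0.669, 0.675),
    eta_se = c(0.637, 0.636, 0.636, 0.636, 0.637, 0.637, 0.637, 0.637,
               0.637, 0.636, 0.636, 0.636, 0.492, 0.477,
               0.636, 0.636, 0.632, 0.492, 0.636, 0.637),
    stringsAsFactors = FALSE
  )
  met <- data.frame(
    target = c("hmgcoa", "mev-R", "orot", "dtmp", "ump", "pe-hs", "glu-L",
               "ser-L", "crm-hs", "sphmyln-hs"),
    kind = "metabolite",
    eta_cv = c(0.712, 0.719, 0.718, 0.719, 0.701, 0.795, 0.783, 0.789,
               0.75, 0.75),
    eta_dv = c(0.668, 0.674, 0.673, 0.665, 0.67, 0.691, 0.663, 0.656,
               0.664, 0.655),
    eta_se = c(0.636, 0.637, 0.637, 0.635, 0.626, 0.7, 0.675, 0.672,
               0.665, 0.658),
    stringsAsFactors = FALSE
  )
  switch(approach, all = rbind(gene, met), gene = gene, metabolite = met)
}
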