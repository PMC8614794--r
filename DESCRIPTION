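Package: fluxtarget
Title: Fuzzy Multiobjective Identification of Anticancer Metabolic Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Searches a paired cancer/normal constraint-based metabolic model
    for gene-, reaction-, and metabolite-centric interventions that abolish
    growth of the cancer model while keeping the perturbed normal model viable
    and metabolically close to its healthy template. Inner problems are flux
    balance analysis (FBA) followed by a quadratic flux-minimization step that
    yields a unique internal flux distribution; candidate interventions are
    scored with a hierarchy of linear fuzzy membership grades aggregated by a
    mean-min rule, and the outer integer search is a nested hybrid
    differential evolution. Includes metabolite-flow (flux-sum) analysis,
    log2 fold changes against the normal template, and iterated
    principal-factor analysis with quartimax rotation, plus a paired toy-model
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
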