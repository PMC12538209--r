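Package: bmapocrm
Title: Partial-Ordering Continual Reassessment Methods with Bayesian Model
    Averaging for Drug-Combination Dose Finding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dose-finding designs for Phase I drug-combination trials in which
    the dose-toxicity ordering is only partially known.  Implements the
    partial-ordering continual reassessment method (POCRM), which selects the
    maximum-posterior ordering before each allocation, and its Bayesian
    model-averaged extension (BMA-POCRM), which mixes the ordering-specific
    posterior distributions of the toxicity probabilities.  Includes
    indifference-interval skeleton construction, enumeration of simple
    orderings for dose matrices, estimation-coherency auditing of sequential
    toxicity estimates, closed-form coherency condition checkers for 2x2
    grids, a seeded trial simulator with operating-characteristic summaries
    (PCS, PAS, POTS, NPTOT, incoherency rates), and replay of completed trials
    from per-dose response streams.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
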