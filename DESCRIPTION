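Package: gtpanel
Title: Design and Evaluation of GTSeq Amplicon Genotyping Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating genotyping-in-thousands (GTSeq)
    amplicon panels for mixed-stock fisheries applications. Provides marker
    quality screening, FST/heterozygosity panel composition, Bayesian genetic
    stock identification with EM mixture estimation and leave-one-out
    simulation, close-kin false-positive power analysis via importance-sampled
    likelihood ratios, Shannon-equitability primer pool optimization,
    inter-run genotype congruence scoring, and hierarchical Balding-Nichols
    simulators that generate truth-known baselines, kin pairs, and read-count
    tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
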