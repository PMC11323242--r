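Package: divhits
Title: Diversity-Aware Benchmarking of Goal-Directed Molecule Generators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: A benchmark harness that measures how many diverse hits a
    goal-directed molecule generator produces under a fixed computational
    budget. Implements the #Circles sphere-exclusion diversity metric (exact
    branch-and-bound and greedy variants), composite filtered scoring with a
    diversity filter, budget-constrained run loops with full per-call audit
    logs, virtual-screening baselines (random order and MaxMin order), a
    reference mutation genetic algorithm, and deterministic synthetic molecule
    libraries with toy bioactivity oracles so the whole pipeline is testable
    offline. Molecule parsing, canonicalization and physicochemical
    descriptors are delegated to OpenBabel via ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
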