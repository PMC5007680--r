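Package: fitflow
Title: Fitness Functions and Fine-Grained Parallel Evaluation Schedules for
    Gene Selection and Biclustering
Version: 0.1.0
Authors@R:
    person("fitflow", "maintainers", email = "fitflow@example.org",
           role = c("aut", "cre"))
Description: Implements two floating-point fitness functions widely used in
    bioinformatics optimization: the weighted gene-subset fitness for
    microarray-based cancer classification (leave-one-out cross-validation
    accuracy combined with a subset-size reward) and the mean squared residue
    (MSR) for biclustering of gene expression data.  Alongside the fitness
    functions it provides a simulator of fine-grained parallel evaluation
    schedules (operator budgets, macro-steps, comparator reduction trees and
    a cycle-level latency/speedup model), a seeded generational evolutionary
    algorithm that exercises both fitness functions, seeded synthetic-data
    generators with planted structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
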