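Package: growSSA
Title: Stochastic Simulation of Gene Circuits in Growing, Dividing Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Maintainer [aut, cre]
Maintainer: Package Maintainer <maintainer@example.org>
Description: An extension of the Gillespie stochastic simulation algorithm
    for bacterial gene-regulation circuits. Cell volume grows exponentially,
    which makes bimolecular propensities time dependent; the next firing
    time is sampled exactly with a Lambert-W closed form. Transcription and
    translation may carry fixed time delays handled through a scheduled
    event queue. Gene copy numbers follow the deterministic
    Cooper-Helmstetter replication schedule, including overlapping cell
    cycles, so that genes near the replication origin reach higher dosage
    than genes near the terminus. Cells divide with binomial partitioning
    of free molecules and full lineage-tree bookkeeping; promoter occupancy
    states are inherited. Optional Ornstein-Uhlenbeck extrinsic noise can
    modulate selected rate constants. Reference solvers (deterministic ODE,
    delay ODE, classic constant-volume SSA, and a dynamic flux-balance
    model) are included as independent oracles, together with packaged
    example systems: a negative autoregulation circuit with and without
    translation delay, a mutual-repression toggle switch colony, and a
    metabolic flux model probing chromosomal gene position.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
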