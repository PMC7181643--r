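Package: starveGASP
Title: Mutation Accumulation and Clonal Expansion in Nitrogen-Starved Quiescent Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference toolkit for the population genetics of
    long-term quiescence in fission yeast. Provides a time-linear mutation
    accumulation clock for nitrogen-starved (G0) cells alongside a
    replication-coupled growth clock, a nutrient-recycling stochastic
    birth-death simulator of starved cultures in which nitrogen released by
    dying cells fuels the clonal expansion of stress- and mitogen-activated
    protein kinase (S/MAPK) pathway mutants (growth advantage in stationary
    phase, GASP), a pooled-colony amplicon sequencing readout with a
    duplicate-concordance low-frequency variant caller, and inference stages:
    preexisting versus de novo origin classification across subcultures,
    viability-phase segmentation of CFU trajectories, clonal expansion
    (doubling time) fitting, and mutation burden and spectrum statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
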