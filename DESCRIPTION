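Package: bdifam
Title: Gene Family Clustering and Birth-Death-Innovation Models for
    Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("bdifam", "maintainers", email = "bdifam@example.org",
           role = c("aut", "cre"))
Description: Clusters protein-coding genes across bacterial and archaeal
    genomes from all-vs-all similarity hits using a reciprocal E-value and
    alignment-length criterion with single-link (connected component)
    clustering, computes pan-genome summary statistics (gene frequency
    spectrum G(k), per-genome family size distributions F(n)), and fits
    stationary birth-death-innovation models (single class, K-class
    mixtures, a generalized rate model, and a discrete power law) to family
    size distributions by maximum likelihood with AIC model selection.
    Includes a synthetic-data module (stationary samplers, an event-driven
    Gillespie simulator of the duplication/deletion/innovation process, and
    planted pan-genome generators) so the whole pipeline is testable
    without genome downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
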