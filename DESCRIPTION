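Package: fredmag
Title: Functional Redundancy of Genome-Resolved Microbial Communities
Version: 0.1.0
Authors@R:
    person("Maintainer", "fredmag", email = "fredmag@example.org",
           role = c("aut", "cre"))
Description: Computes potential and expressed functional redundancy (FRed)
    of microbial communities from metagenome-assembled genome (MAG) trait
    tables and abundance matrices. Converts annotation hit tables into
    completeness-normalized trait tables, builds Euclidean trait distance
    matrices, and derives per-sample richness, Gini-Simpson diversity,
    Rao's quadratic entropy, uniqueness and FRed across trait subsets
    (energy, substrate, CO, H2, N, S, CAZymes). Expressed redundancy is
    estimated from TPM-normalized transcript counts. Includes the
    comparative statistics used to relate redundancy to environmental
    drivers (Wilcoxon rank-sum, Cliff's delta, Pearson correlation, OLS
    models with a collinearity screen, permutation PERMANOVA) and a seeded
    synthetic-community generator with controlled guild-redundancy
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
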