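Package: salivafam
Title: Household and Host-Genetic Variance Partitioning of Family
    Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for partitioning variation in microbial community
    composition between shared environment (household, city) and host
    genetics within extended families.  Provides a sequential
    (Type-I) permutational multivariate analysis of variance on
    distance matrices with strata-restricted permutations, pedigree
    and SNP-based kinship estimation with metric multidimensional
    scaling covariates, Bray-Curtis dissimilarities (community-wide
    and within-genus), Mantel tests, spouse-pair contrasts, and a
    variable-order robustness procedure with false-discovery-rate
    control.  Includes a synthetic-cohort generator (multigenerational
    pedigrees, gene-dropped genotypes in haplotype blocks,
    Dirichlet-multinomial phylotype count tables with configurable
    household, city, age, and genetic variance components, spiked
    amplicon reads) and the read- and sample-level quality-control
    filters used in family amplicon studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
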