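Package: hydropop
Title: Population Genetic Structure Across Watershed Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-scale population genetic analysis of freshwater
    organisms sampled across hydrographic (watershed) boundaries. Reads
    diploid microsatellite genotypes (Genepop dialect) and aligned mtDNA
    sequences, computes per-population diversity (observed and unbiased
    expected heterozygosity, rarefaction allelic richness, exact
    Hardy-Weinberg tests, EM null-allele estimation), between-population
    differentiation (Weir-Cockerham theta with permutation tests, R_ST and
    the allele-size permutation test, hierarchical AMOVA with F_CT,
    isolation-by-distance with Mantel tests), individual-based Bayesian
    admixture clustering with Evanno's delta-K and greedy replicate
    alignment, factorial correspondence analysis, median-joining haplotype
    networks, and coalescent simulation under the generalized stepwise
    mutation model feeding approximate Bayesian computation for demographic
    model choice and parameter estimation. Includes a synthetic-data
    generator emulating a 27-population, three-watershed sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    geosphere,
    graphics,
    grDevices,
    jsonlite,
    nnet,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
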