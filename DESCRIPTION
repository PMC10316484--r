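Package: seascaper
Title: Seascape Genetics of Clonal Marine Plants: Clonal Diversity,
    Differentiation, Dispersal Simulation and Variance Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end seascape-genetics toolkit for clonal marine
    organisms genotyped at codominant microsatellite loci. Reads
    GenAlEx-dialect genotype tables, assigns multilocus genotypes (MLGs) and
    clonal richness with probability-of-identity and P_sex diagnostics,
    estimates per-site diversity (observed and Nei unbiased heterozygosity,
    rarefied allelic and private-allele richness, Weir-Cockerham F_IS,
    Kalinowski-Taper null-allele maximum likelihood, standardized index of
    association), quantifies differentiation (Weir-Cockerham F_ST with
    permutation tests, G_ST-H_S mutation-bias correlation, Smouse-Peakall
    individual spatial autocorrelation, Evanno delta-K), simulates propagule
    dispersal on gridded currents (RK4 advection with a random-walk
    diffusivity) to build directed oceanographic connectivity matrices and
    least-cost overwater distances, summarises connectivity as network
    metrics, and partitions genetic differentiation into geographic,
    oceanographic and environmental components with partial redundancy
    analysis.  A synthetic-data module generates genotypes (Balding-Nichols),
    velocity fields and environmental covariates with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    ape,
    cluster,
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
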