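Package: counselnet
Title: Leaky Noisy-OR Bayesian Networks for Genetic Counseling in Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds small pedigree-structured discrete Bayesian networks for
    genetic counseling on autosomal diallelic disease loci, with degenerative
    myelopathy in dogs as the running example. Phenotype nodes are modelled
    with leaky noisy-OR gates whose leak and link probabilities carry Beta
    priors; genotype transmission follows Mendelian inheritance; founder
    genotypes take uniform or Hardy-Weinberg priors. Provides exact inference
    (variable elimination, checked against exhaustive enumeration), Monte
    Carlo propagation of prior uncertainty into risk summaries, optional
    genetic-test nodes with sensitivity and specificity, and an expected
    utility layer for comparing mating decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
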