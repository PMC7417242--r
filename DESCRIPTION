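Package: kinrecruit
Title: Kin-Structured Larval Recruitment Inference for Reef Fish Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether coral reef fish larvae recruit alongside their kin
    more often than chance. Converts colony fecundity, larval survival and
    habitat geometry into the size and family structure of a theoretical total
    recruiting cohort (TRC), draws light-trap-sized subsamples from it without
    replacement to build Monte Carlo sibship nulls (with the exact multivariate
    hypergeometric expectation as an oracle), implements the radius-halving
    rate statistic and its forward/inverse radius-area-cohort conversions, and
    scores empirical sibship compositions against the null with a permutation
    tail test and a confidence search for the largest compatible cohort.
    Includes sibship-graph summaries from pairwise assignments, a pairwise
    IBD-class relatedness classifier for biallelic SNP panels, standard
    population-genetic summaries (effective alleles, heterozygosity, F
    statistics, multilocus probability of identity), a Mendelian colony
    pedigree and genotype simulator, and Genepop/CSV genotype input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
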