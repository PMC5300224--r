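Package: breedcomp
Title: Breed Composition and Introgression Analysis for Composite Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the introgression of founder breeds in
    composite cattle populations from SNP genotypes.  Provides PLINK-format
    genotype input/output and quality control, heterozygosity and exact
    Hardy-Weinberg testing, pairwise Fst, genomic-relationship PCA with
    outlier exclusion, linkage-disequilibrium statistics with sliding-window
    pruning and Sved effective-population-size trajectories, and three
    independent ancestry estimators: a maximum-likelihood admixture model
    fitted by EM with cross-validation over the number of populations, a
    Bayesian admixture model fitted by Gibbs sampling, and a single-regression
    breed-composition method.  A synthetic-data module simulates purebred
    reference panels and admixed cohorts with known ancestry, including the
    crossing schemes that produce the Canchim composite breed, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
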