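Package: polyLD
Title: Population Structure and Linkage Disequilibrium for Mixed-Ploidy SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing biallelic SNP-array genotypes from panels that
    mix diploid and autotetraploid individuals, where tetraploid heterozygous
    dosage classes are collapsed to a single heterozygous call. Provides a
    genotype-panel container with TSV and VCF ingestion, presence/absence
    encoding with mean imputation, diversity summaries (heterozygosity,
    polymorphism sharing), principal component analysis, model-based Gaussian
    mixture clustering selected by BIC, Nei (1972) standard genetic distances,
    neighbor-joining trees, maximum-likelihood r2 between unphased loci via an
    EM algorithm, nonlinear fitting of linkage-disequilibrium decay against
    physical distance under drift-recombination equilibrium (Sved and
    Hill-Weir expectations), cross-population LD-consistency correlations, and
    forward-in-time Wright-Fisher and Balding-Nichols simulators that supply
    truth-backed panels for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    vcfR,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
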