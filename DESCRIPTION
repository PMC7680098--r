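Package: ramet
Title: Ploidy Inference and Clonality Testing for Reduced-Representation
    Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of mixed-ploidy ddRAD-seq genotype matrices for
    clonality studies of patterned vegetation, such as the perennial
    grasses ringing Namib Desert fairy circles. Infers per-sample ploidy
    from allele-balance spectra and per-locus haplotype counts, recodes
    genotypes into a ternary code robust to homoeologous variation,
    quantifies genetic relatedness by hierarchical clustering of
    Euclidean distances, tests for clonal structure with minimum
    within- versus between-circle distances and a Wilcoxon rank-sum
    test, fits a genetic-versus-spatial distance-decay regression, and
    estimates method-of-moments inbreeding coefficients. Includes a
    synthetic-population generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
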