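Package: oatvigor
Title: Image-Based Seed Vigor Phenotyping and Iterative Mixed-Model GWAS for Oat
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of seed vigor in hexaploid oat panels grown
    in germination pouches: segmentation of root and shoot structures from
    pouch images by median-scaled thresholding and particle filtering,
    derivation of vigor traits (root surface area, growth rates, shoot
    length) with quality-control rules, batch adjustment and broad-sense
    heritability under an augmented design with replicated checks, an
    iterative fixed/random-effect association scan (FarmCPU-style) with
    pseudo-QTN kinship and principal-component structure correction,
    Bonferroni and FDR thresholds, and post-GWAS summarization of unique
    loci, homeologous region sets and allele contrasts. Includes a synthetic
    data generator (pouch images with exact ground truth, structured inbred
    SNP panels, phenotypes with planted QTN) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    yaml,
    vcfR,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jpeg,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
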