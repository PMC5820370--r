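Package: exolink
Title: Family-Based Exome Variant Prioritization and Parametric Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variant prioritization and two-point parametric linkage
    analysis for multiplex families studied by whole-exome sequencing.
    Provides a filtering cascade over annotated multi-sample VCFs
    (affected-sharing intersection, population and in-house frequency
    filters, region and consequence filters, and a Grantham/phyloP
    candidate rule), Grantham physicochemical amino-acid distances,
    dominant and recessive segregation checks with a population control
    screen, exact two-locus pedigree likelihoods by Elston-Stewart
    peeling with LOD curves and structural maximum-LOD ceilings, sibship
    haplotype-sharing reconstruction for microsatellite markers, and a
    seeded gene-dropping simulator that generates complete synthetic
    studies (PED, annotated VCF, marker genotypes, control cohort) for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
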