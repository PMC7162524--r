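Package: eubpop
Title: Population Genomics of Wild Saccharomyces eubayanus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genomic analysis of largely homozygous wild
    yeast panels: VCF ingestion with repeat/coverage/heterozygosity masking,
    per-window nucleotide diversity, Watterson's theta, Tajima's D, Hudson's
    F_ST and LD decay, minimum-divergence ancestry painting of admixed
    strains, introgression-tract detection from dual-reference read depth,
    isolation-by-distance Mantel tests, latitude-split diversity summaries,
    and host/substrate association testing. Includes a structured-population
    genotype simulator (nested Balding-Nichols drift with clonal admixed
    lineages, heterospecific tracts, and spatially structured variation) so
    every estimator can be validated against generative truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    IRanges,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    vegan,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
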