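Package: cosegscan
Title: Co-Segregation Scanning and Marker Design for Recessive
    Monogenic Traits in Biparental Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-trait analysis for a recessive trait controlled by a
    single major gene in biparental plant populations, as used in
    map-based marker development for the hydrangea double-flower loci.
    Reads VCF genotype calls and phenotype tables, applies per-call read
    depth and per-site missingness filters, scores every SNP for its
    degree of agreement with the recessive single-locus model, reports
    co-segregating marker sets and the physical locus interval, designs
    CAPS markers by in-silico restriction digestion, predicts INDEL
    marker allele sizes, calls genotypes from observed fragment sizes,
    and classifies accessions for marker-assisted selection.  A
    configurable F2/backcross population simulator with Haldane
    recombination, read-depth noise and missingness provides fully
    synthetic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    Biostrings,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
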