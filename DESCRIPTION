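Package: introscan
Title: Introgression Mapping with Windowed Divergence, f_d and Topology Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps introgressed loci from backcross-introgression breeding
    designs using whole-genome genotype data from four lineages (recipient,
    introgressed line, donor, outgroup). Implements windowed Nei's absolute
    divergence (d_XY), nucleotide diversity (pi), Patterson's D and the f_d
    introgression estimator, quartet topology weighting of neighbor-joining
    local trees, concordance-based candidate-region extraction with fine-scale
    boundary refinement and homozygosity checks, and coding-sequence
    consequence annotation of candidate null mutations. A forward simulator of
    the recessive-phenotype-selected backcross breeding design provides
    planted-locus ground truth so every pipeline stage is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
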