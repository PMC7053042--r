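Package: poolDiversity
Title: Pooled Whole-Genome Sequencing Diversity Analysis for Structured Germplasm
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates population-genetic diversity from pooled whole-genome
    sequencing (pool-seq) of structured germplasm collections. Provides pooled
    allele-frequency estimation from per-sample allelic read depths, gene
    diversity (expected heterozygosity, 2pq) with hierarchical lineage
    summaries, classification and tallying of lineage-specific (private,
    fixed) variation across a species / crop-type / accession hierarchy,
    shared-variation relationship matrices with neighbor-joining trees and
    site-bootstrap support, allele-frequency principal component analysis by
    singular value decomposition, and hierarchical AMOVA for pooled frequency
    data. A Balding-Nichols hierarchical simulator with ground truth makes
    every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
biocViews: Genetics, PopulationGenetics, SNP, Sequencing, VariantAnnotation
RoxygenNote: 7.3.3
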