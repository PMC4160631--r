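Package: stressSmallRNA
Title: Stress-Responsive Small RNA Classification and Factorial
    Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for small-RNA sequencing libraries from
    abiotic-stress experiments and for factorial (genotype x treatment)
    expression microarrays of flower buds. Reads are collapsed to unique
    signatures, mapped exactly to a genome on both strands, cleared of
    structural RNAs (tRNA/rRNA/snoRNA/snRNA), grouped into loci under a
    <150 nt gap rule, classified by genomic category, normalized against
    per-library miRNA totals, and tested for stress-responsive families
    with exact hypergeometric tail tests. The expression side provides
    75th-percentile normalization, vectorized balanced two-way ANOVA with
    Benjamini-Hochberg FDR, genotype/treatment log2-ratio scatter pairs
    with per-GO-set correlation, a Pearson coexpression screen, promoter
    scanning for the auxin response element, and delta-delta-Ct relative
    quantification. A synthetic-data module generates annotated toy
    genomes, stress-shifted read libraries, and factorial matrices with
    full ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
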