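Package: bulkscan
Title: Bulked-Segregant Variant Prioritization for Mapping-by-Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate causal mutations for a recessive phenotype
    from mutant and wildtype bulk sequencing of a selfed mutagenized family.
    Implements hard filtering of per-bulk variant calls (allele balance,
    depth, genotype quality, quality-by-depth), restriction to
    missense/frameshift consequences, subtraction of calls shared between
    bulks, and exact-binomial scoring of each surviving candidate against
    the allele-read fractions Mendelian segregation predicts for each bulk.
    Also detects large deletions as zero-coverage or zero-expression runs
    over gene models, predicts coding consequences (frameshift, premature
    stop, protein truncation) from CDS sequences, and ships a synthetic-data
    generator emulating pooled sequencing of a 3:1 segregating family for
    validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), methods, GenomicRanges
Imports:
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
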