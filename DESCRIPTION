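Package: pangenekit
Title: Pan-Genome Comparison of Reference-Anchored Plant Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing a desk-scale pan-genome from
    reference-anchored genotypes of a triplicated plant genome. Merges and
    filters assembly-based variant calls from two callers, reconstructs
    pseudo-genomes with a coordinate liftover map, classifies variants by
    genomic region and coding effect, compares gene annotations at several
    minimum-overlap thresholds, detects positional orthologs by reciprocal
    best Smith-Waterman hits constrained to the same chromosome, partitions
    genes into common, dispensable and unique sets, calls retained and lost
    genes against outgroup proteomes, and transfers subgenome assignments.
    Includes a genome simulator that emits every pipeline input together with
    ground-truth tables so the whole workflow can be validated end to end.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    Rcpp,
    yaml,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
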