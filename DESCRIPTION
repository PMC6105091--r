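Package: txloom
Title: Integration of Multiple Transcript Assemblies into a Consolidated Gene Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consolidates transcript models produced by different RNA-seq
    assemblers, samples or sequencing technologies into a single coherent
    gene annotation. The pipeline validates and standardizes input models
    (strand correction from splice-site canonicity, removal of exact
    duplicates, length filtering), attaches external evidence (trusted
    splice junctions, open reading frames, protein homology), scores
    transcripts on configurable metrics evaluated relative to their locus,
    resolves chimeric models by splitting at ORF boundaries, selects a
    primary transcript plus valid splice variants per locus, and compares
    any annotation against a reference with class codes and recall,
    precision and F1 statistics at base, exon, intron, intron-chain,
    transcript and gene level. A seeded synthetic-data generator produces
    toy genomes, truth annotations and assembler-like corrupted transcript
    sets for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
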