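Package: repeatscape
Title: De Novo Repeat Landscape Annotation and Validation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-processing de novo repeat annotations of
    assembled genomes: classification of tandem-repeat detections into
    simple repeats, microsatellites, minisatellites, large tandem repeats
    and satellite DNAs; attribute-aware GFF interval algebra including
    stack resolution, juxtaposition merging and long-join copy counting;
    dark-matter mining by seed-and-extend re-annotation with well-conserved
    probe copies; N-gap strip/restore coordinate remapping; permutation
    tests for chromosomal enrichment and 50-kbp hotspot detection; and a
    synthetic genome simulator with planted, ground-truthed repeats for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
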