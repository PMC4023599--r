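Package: bzipkit
Title: Genome-Wide Analysis of Plant bZIP Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for genome-wide characterization of basic leucine
    zipper (bZIP) transcription factor gene families. Detects and annotates
    the bZIP domain by its structural grammar (basic region N-x7-R/K,
    hinge, leucine-zipper heptad repeats), classifies leucine-zipper length
    gradients, reports DNA-binding residue substitutions and
    phosphorylation-site motifs, computes intron positions and phases
    within the domain and classifies genes into nine intron/exon structural
    patterns, summarizes chromosomal distribution, tandem arrangement and
    collinearity, assigns phylogenetic groups against labeled reference
    proteins via a neighbor-joining tree, and analyses expression data
    (thresholded Pearson co-expression, 2^-ddCt qRT-PCR quantification,
    stress-responder calling and expression clustering). Includes
    generators for fully synthetic inputs with planted ground truth and a
    packaged family table for the grapevine (Vitis vinifera) bZIP family.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
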