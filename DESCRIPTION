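Package: ltrnest
Title: Structural Typing and Nested-Layer Reconstruction of LTR
    Retrotransposons from Repeat Alignments
Version: 1.0.0
Authors@R:
    person("ltrnest", "developers", email = "ltrnest@example.org",
           role = c("aut", "cre"))
Description: Post-processes family-library alignments of long terminal
    repeat (LTR) retrotransposon consensus sequences against a genome
    (RepeatMasker '.out' tables) into structurally annotated elements.
    Overlapping hits are resolved, split hits are defragmented into
    candidate LTR and internal-region pieces, and candidates are chained
    by a discriminating tree that assigns link states (linked, not
    linked, inserted) so that full-length, solo-LTR, truncated and
    shared-LTR complex elements are recovered together with their nested
    insertion layers. Elements with two or more LTRs are dated from
    intra-element LTR divergence under the Kimura two-parameter model
    (T = K/2r).  A seeded simulator plants structurally diverse and
    nested elements in synthetic genomes and emits exact alignments so
    the whole pipeline is testable without external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
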