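Package: pausetrans
Title: Transcriptional Pausing State Calls and Transition Analysis for
    Promoter ChIP and 3' Transcript Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies protein-coding loci into active, paused and silent
    transcriptional states by combining a dual-threshold H3K4me3 promoter
    metagene binding call (log2 enrichment over pan-histone H3) with
    full-length transcript detection against negative-control probes on
    bead expression arrays.  Quantifies the nine possible state
    transitions between two cell populations, summarises them as
    activation, silencing, priming (silent to paused) and archiving
    (paused to silent), and profiles transitions by Gene Ontology term to
    anticipate lineage fate.  Includes a synthetic-data generator that
    emulates both array platforms from a known ground truth so the whole
    chain can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
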