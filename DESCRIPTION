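Package: cleavemap
Title: Endoribonuclease Cleavage-Site Mapping and Motif Discovery from
    Coverage Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for determining the recognition motif of a
    sequence-specific endoribonuclease (such as the MazF toxin of type II
    toxin-antitoxin systems) from massively parallel sequencing of
    digested synthetic RNA substrates.  Cleavage-generated 5' ends are
    marked by barcode ligation, reads are mapped back to the known
    substrates, and cut sites are called from the relative coverage
    increase (RCI) statistic, the per-position ratio of read depth to the
    depth one base upstream.  Windows around the top-ranked sites yield a
    position frequency matrix and a consensus motif; a fluorometric
    (FRET) probe set is designed to verify the low-consistency motif
    positions; coding sequences are scanned for motif prevalence against
    a base-composition null; and a global-alignment utility reports
    percent identity and similarity for protein pairs.  A seeded
    synthetic-data generator emulating partial digestion, size selection,
    barcode ligation and read sampling makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
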