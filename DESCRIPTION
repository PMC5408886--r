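Package: allosite
Title: Mapping the Common Allosteric Site of Class C GPCRs from
    Structures and Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates receptor-modulator crystal-structure contacts with
    curated single-point mutagenesis data to delineate the transmembrane
    allosteric modulator site shared across class C G protein-coupled
    receptors.  Provides segment-anchored generic residue numbering, a
    distance-rule contact extractor for PDB complexes, fold-change effect
    calling for mutation tables, evidence integration into a per-position
    site profile with hotspot and Venn statistics, UPGMA family trees with
    a monophyly check, physicochemical column conservation, and a
    synthetic-data generator that plants a known site so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
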