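Package: plastcomp
Title: Comparative Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated chloroplast
    (plastid) genomes: detection of the quadripartite structure (large and
    small single-copy regions and the inverted repeat pair), MISA-style
    simple sequence repeat scanning with species-discriminating marker
    search, REPuter-style dispersed repeat detection, SNP and indel calling
    from whole-genome multiple alignments stratified by annotation class,
    exhaustive SNP-density hotspot discovery, and a light distance-based
    phylogeny. Includes a synthetic plastome simulator that emits annotated
    genomes, true alignments and ground-truth mutation records so every
    stage of the pipeline can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
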