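Package: cpdiff
Title: Pairwise Plastome Comparison, cpSSR Survey and Statistical-Parsimony
    Haplotype Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of pairs of aligned plastid (chloroplast)
    genomes: enumeration and classification of SNPs (transition/transversion,
    region, genic context, synonymous/nonsynonymous effect), indels and minute
    inversions; detection of length-polymorphic chloroplast microsatellites
    (cpSSRs); hairpin (stem-loop) tests around minute inversions; region- and
    context-stratified divergence statistics and variable-window ranking for
    marker design; and haplotype collapsing with statistical-parsimony
    (TCS-style) network construction treating gaps as a fifth state and each
    indel as a single mutational event. A seeded synthetic plastome-pair and
    haplotype-sample generator with fully known planted truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
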