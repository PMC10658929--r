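Package: karyevo
Title: Comparative Karyotype Evolution with Ancestral Elements and a
    Fusion/Fission Chromosome Nomenclature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying chromosome evolution in clades with deeply
    conserved synteny (moths and butterflies in particular). Extant
    chromosomes are assigned to numbered ancestral elements by shared
    orthologous gene content, decomposed into element segments, and renamed
    with a fusion/fission ("f"/"d") grammar. Independent fusion and fission
    events are placed on a species tree by parsimony, inter-chromosomal gene
    movements are detected and classified as copy- or cut-type, gene loss
    and duplication are tallied per element, collinear blocks and synteny
    breakpoints are chained from orthologous gene anchors, and
    transposable-element enrichment in breakpoint regions is tested by
    seeded permutation. A karyotype-evolution simulator with complete truth
    logs supports ground-truth validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
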