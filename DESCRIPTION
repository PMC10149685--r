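Package: ClpTyper
Title: Classification and Comparative Sequence Analysis of Clp/Hsp100
    Unfoldase Paralogs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for sorting double-ringed Clp/Hsp100 AAA+ unfoldase
    paralogs (ClpB, ClpC and the ClpI class found in Actinomycetota) from
    protein sequence alone. Implements reference bit-score partitioning of
    cohorts against ClpC and ClpB references, diagnostic feature detection
    (Walker A/B motifs, M-domain length, LGF-loop motifs, N-terminal domain
    conservation), BLOSUM62 column-profile conservation scoring with
    profile-profile cross-alignment of multiple sequence alignments,
    taxonomic occurrence tables, and neighbor-joining phylogenies with
    bootstrap-confirmed subgroup calling. Ships a synthetic Clp-family
    cohort generator with ground-truth labels, taxonomy and domain
    coordinates so the full analysis is exercisable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
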