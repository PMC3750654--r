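Package: ontomatrix
Title: Gene Ontology Ancestor Closure and Binary Membership Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links GO-annotated genes to all ancestor classes of any OBO 1.2
    structure file and emits gene-by-GO-class binary membership matrices in
    sparse triplet or full grid form, for import into R, Matlab or Python
    analysis environments. Includes a memoized ancestor-closure engine whose
    work is bounded by ontology size rather than input size, readers for
    generic tab-separated annotation files and GAF 2.x association files,
    an ontology-version diff utility quantifying GO class turnover between
    OBO releases, and a seeded synthetic-fixture generator producing valid
    OBO, TSV and GAF files with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
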