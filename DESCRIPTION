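Package: dcjtopo
Title: Genome Rearrangements, Halving and Median Problems via Polygon Gluings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of circular genomes under the
    double-cut-and-join (DCJ) model: breakpoint and contracted breakpoint
    graphs, DCJ distances and shortest scenarios, genome halving after
    whole-genome duplication, exact counting of halving solutions and
    intermediate genomes via Catalan-type formulas, and a topological solver
    for the restricted guided halving and intermediate genome median problems
    based on polygon gluings, embedded graphs on orientable surfaces, and
    DCJ-surgeries (torus single-face case).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
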