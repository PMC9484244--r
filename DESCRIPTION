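Package: ambb
Title: Adjacency Difference Matrix Binary Biclustering for Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Binary biclustering of gene expression matrices with the
    adjacency difference matrix (AMBB) approach: Bimax-style binarization of
    expression data, seed-driven row expansion under a Hamming-distance row
    threshold, column expansion under an automatically scheduled column
    threshold, and recursive refinement to all-ones submatrices. Includes
    semi-automatic row-threshold selection, Prelic-style match score with
    Recovery and Relevance, an exact hypergeometric enrichment p-value,
    a synthetic benchmark generator that implants constant, shift, scale and
    shift-scale biclusters (optionally overlapping) into noisy backgrounds,
    a benchmark driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
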