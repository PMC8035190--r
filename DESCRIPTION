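Package: pequant
Title: Quantification of Prime-Editing Outcomes from Amplicon and UDiTaS Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequencing-based quantification of prime-editing outcomes at
    targeted loci. Implements amplicon-mode analysis (paired-end merging,
    quality filtering, affine-gap global alignment, per-read precise-edit and
    indel calling, per-base indel cataloguing with triplicate-control
    background subtraction) and UDiTaS-mode analysis (UMI-family collapsing,
    exemplar classification into precise edit, small indel/substitution,
    pegRNA-nick deletion, large deletion and AAV-integration categories,
    split-read breakpoint detection, and Benjamini-Hochberg-gated recurrent
    deletion calls), together with a ground-truth synthetic library generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    stringi,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readr,
    withr
Config/testthat/edition: 3
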