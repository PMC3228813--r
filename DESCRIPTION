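Package: pclouds
Title: De Novo Repeat Annotation with Oligonucleotide Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo and element-specific annotation of repetitive sequence
    in genomes by clustering high-copy fixed-length oligonucleotides into
    "clouds", demarcating cloud-dense regions, calibrating length-dependent
    false-positive probabilities against a dinucleotide-preserving null
    genome, and assigning each annotated region a posterior probability of
    being truly repetitive.  Includes a fragment-sensitivity benchmarking
    harness, a missed-repeat estimator, and a synthetic-genome generator
    with planted repeat families for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
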