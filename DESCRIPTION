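Package: wgdtrace
Title: Paleopolyploidy Detection, Ks Dating, Fractionation Modelling and
    Karyotype Event Calculus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for reconstructing the polyploid
    history of a plant genome from gene order and coding sequence alone:
    dynamic-programming detection of collinear (synteny) blocks from BLAST
    tabular hits, Nei-Gojobori (NG86) Ka/Ks estimation with Jukes-Cantor
    correction, Gaussian-mixture fitting of block-median Ks distributions with
    rate correction and proportional dating against the core-eudicot
    hexaploidy, geometric run-length modelling of post-polyploidy gene loss
    (fractionation), orthologous-ratio estimation from dot plots, a
    telomere-centric karyotype event engine (end-to-end joining, nested
    chromosome fusion, reciprocal-translocation crossover, inversion,
    whole-genome duplication and triplication) with fusion-timing inference,
    and a genome-evolution simulator producing full ground truth for
    validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
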