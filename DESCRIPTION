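Package: orfselect
Title: Validation of Predicted Proteins by Selection-Pressure Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates predicted open reading frames (ORFs) from pairs of
    homologous coding sequences. Counts synonymous and nonsynonymous sites
    and substitutions over a codon-aware pairwise alignment, forms the
    selection pressure omega = dN/dS, casts the substituted versus
    non-substituted position counts into a 2x2 contingency table, and uses
    Fisher's exact test to decide whether omega departs significantly from
    one. Includes a CODEML pairwise-output parser, codon adaptation index
    and G+C annotations, Kolmogorov-Smirnov comparisons between verdict
    groups, and a codon-evolution simulator for measuring the test's
    type-I error and power.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
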