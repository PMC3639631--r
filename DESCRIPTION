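Package: fractalseq
Title: Fractal Dimension and Entropy Profiling of Nucleotide Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Profiles nucleotide sequences by the Higuchi fractal dimension
    of their atomic-number encoding and by Shannon mono- and dinucleotide
    entropy, and compares messenger RNA against embedded coding sequences
    (CDS) to probe the noncoding remainder. Includes paired mRNA/CDS
    loading from FASTA plus a coordinate manifest, ordinary least squares
    with adjusted R-squared, sample skewness of expression distributions,
    fractal-dimension/entropy maps with designated-outlier handling, and
    seeded synthetic generators (i.i.d. and Markov nucleotide sequences,
    fractional Brownian motion, planted-relation mRNA/CDS panels, and
    expression tables with controlled skewness) so every analysis stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
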