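Package: sirnadesign
Title: Functional siRNA Selection with Seed-Dependent Off-Target Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing highly functional small interfering RNAs
    (siRNAs) with reduced seed-dependent off-target activity. Enumerates
    candidate 21-nt siRNA duplexes (2-nt 3' overhangs) from a target mRNA by
    sliding a 23-nt window, evaluates four empirical sequence-asymmetry rules
    on the guide strand, and filters candidates by the nearest-neighbor
    melting temperature of the 7-bp duplex formed between the guide seed
    region (positions 2-8) and its target. Ships the Freier et al. (1986)
    RNA/RNA nearest-neighbor parameter table, enumerates the full 7-mer seed
    space, and audits 3'-UTR collections for seed-complementary heptamer
    sites classified by seed-duplex stability.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
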