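Package: repairsigs
Title: Mutational Signatures of Concurrent Polymerase-Proofreading and
    Mismatch-Repair Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing tumors that have lost both DNA
    polymerase proofreading (POLE/POLD1 exonuclease domain mutation) and
    mismatch repair (microsatellite instability). Builds pentanucleotide
    plus indel mutation catalogs (1536 SNV channels and 8 indel size
    channels), discovers mutational signatures by Bayesian non-negative
    matrix factorization with automatic relevance determination, matches
    discovered signatures to a reference database with a
    cosine-maximizing two-signature combination fit and a
    channel-shuffling permutation null, computes replication-timing
    enrichment and leading/lagging replicative strand asymmetry profiles
    with bootstrap errors, and orders repair-deficiency events from
    mutation clonality with a Poisson ratio-resampling test. Includes a
    fully specified synthetic cohort generator with ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    withr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
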