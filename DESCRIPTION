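Package: medspell
Title: Spelling Correction for Health Search Queries by Phonetic and
    Approximate String Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Corrects misspelled queries submitted to medical search tools in
    French by combining phonetic transcription with two approximate string
    comparators: the normalized Levenshtein edit distance and the Stoilos
    (ISub) label similarity, applied against a normalized medical term
    dictionary. Provides query normalization and segmentation, a French
    medical phonetic encoder alongside classic Soundex, tiered dictionary
    lookup (exact, phonetic, approximate), bag-of-words multi-word term
    matching, a precision/recall/F-measure evaluation harness with threshold
    sweeps and Wald confidence intervals, and a seeded synthetic misspelling
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
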