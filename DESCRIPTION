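Package: lncwave
Title: Wavelet-Based Coding-Potential Classification of Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Distinguishes long non-coding RNAs (lncRNAs) from
    protein-coding RNAs using seven multi-scale features extracted from
    the column-summed generalized Morse wavelet scalogram of a numerically
    encoded transcript, combined with eight classic coding-potential
    features (ORF structure, Fickett TESTCODE statistic, peptide
    isoelectric point, composition). Features pass a Pearson correlation
    screen and feed a random-forest classifier evaluated with rank-based
    AUC and confusion-matrix metrics. Includes a seeded simulator of
    coding-like and noncoding-like transcripts so the full pipeline is
    testable without external datasets, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
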