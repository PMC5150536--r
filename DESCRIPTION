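Package: enhancr
Title: Two-Layer Sequence-Based Enhancer Classification with Bi-Profile
    Bayes Features and F-Score Wrapper Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies fixed-length DNA fragments first as enhancers versus
    non-enhancers and then, for predicted enhancers, as strong versus weak,
    using a radial-basis-function support vector machine cascade. Sequences
    are encoded by bi-profile Bayes positional probabilities, mononucleotide
    composition, and overlapping trinucleotide (pseudo-nucleotide)
    composition; discriminative features are chosen by an F-score-ranked
    two-step wrapper (coarse threshold scan, fine dimension scan) plus a
    greedy cross-family combination step, all driven by jackknife accuracy.
    Includes leave-one-out and stratified k-fold evaluation reporting
    sensitivity, specificity, accuracy, and the Matthews correlation
    coefficient, and a synthetic-sequence generator with controllable
    positional, compositional, and trinucleotide signal for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
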