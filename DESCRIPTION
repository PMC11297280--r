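Package: smst
Title: Stimulus Construction, Simulation and Scoring for the Semantic
    Mnemonic Similarity Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing semantic Mnemonic Similarity
    Task (sMST) experiments. Loads word2vec-format word embeddings and
    measures semantic similarity of adjective-noun phrases as the cosine of
    their summed word vectors; filters a psycholinguistic lexicon by
    frequency percentile, length, syllable count and phonological
    neighbourhood; assembles target / close-lure / distant-lure triplets and
    foils from cosine-similarity bands; produces counterbalanced,
    pseudorandomised encoding and recognition lists with exact
    exposure equalisation across participants; simulates recognition
    responses from a probit signal-detection model with
    similarity-dependent familiarity and age-group effects; and scores and
    models the results (per-condition 'old' proportions, d-prime contrasts,
    lure discrimination index, a fixed-effects probit similarity-by-age
    model, Mahalanobis outlier screening, and Fisher z comparison of
    correlations). A synthetic-data generator emulates a clustered
    embedding space and a realistic lexicon so the whole pipeline can be
    exercised without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
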