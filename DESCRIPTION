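Package: swbgrowth
Title: Lexicon-Based Subjective Well-Being Scoring and Latent Growth
    Trajectory Modelling for Social-Media Post Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to measure subjective well-being (SWB) from streams of
    social-media posts and to model its development over the phases of a
    public-health emergency. The pipeline cleans and tokenizes posts,
    builds a three-dimension SWB lexicon (life satisfaction, positive
    affect, negative affect) by expanding seed words through word-embedding
    neighbourhoods, classifies posts into high/low levels per dimension
    with TF-IDF features and a grid-searched radial-kernel support vector
    machine, aggregates predicted labels into a per-user per-phase SWB
    count score, and fits linear latent growth curve models (LGCM) by
    maximum likelihood and latent growth mixture models (LGMM) by EM,
    including class enumeration with information criteria, relative
    entropy, the Lo-Mendell-Rubin approximate test and the parametric
    bootstrap likelihood ratio test. A synthetic-data module generates
    corpora, embeddings and trajectory matrices with known ground truth so
    that every stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
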