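Package: promod
Title: Promoter Modeling of Gene Expression from Transcription Factor
    Binding Site Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the linear relationship between gene expression and the
    transcription-factor binding site (TFBS) content of proximal promoters.
    Scores promoters with TFBS-gene association scores (TGAS schemes I-V,
    combining motif match scores, positional bias weights, TF expression
    fold changes and TF-TF interaction probabilities), infers pairwise TF-TF
    interaction probabilities from binary promoter-occupancy matrices via
    backward-eliminated hierarchical log-linear models inside an iterative
    random-sampling wrapper, and explains expression of differentially
    expressed gene classes with AIC-reduced linear regressions extended by a
    cross-validation-gated random search over pairwise TFBS terms. Ensembles
    of regression coefficients over repeated seeded runs yield statistically
    tested TFBS activities, activity changes between conditions, and TF-gene
    networks. A seeded synthetic-data generator with known ground truth makes
    every stage testable without external data.
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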