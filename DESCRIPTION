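Package: drquant
Title: Automated Quantification of Desmoplastic Reaction at the Colorectal Tumour Front
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies desmoplastic reaction (DR) on haematoxylin-and-eosin
    slide imagery of the colorectal cancer invasive front. From an
    invasive-front annotation and a myxoid-stroma segmentation mask the
    package constructs outward margin bands (500 and 1000 micrometres),
    measures object-level myxoid stroma area features (total, average and
    largest single area per margin), classifies DR as immature versus other
    by area cut-offs, and evaluates prognostic significance with maximally
    selected rank statistic cut-point discovery, Kaplan-Meier estimation,
    log-rank tests, univariate and forward-stepwise Cox proportional-hazards
    models and Benjamini-Hochberg correction. A pluggable segmenter
    interface ships with a lightweight colour-and-texture pixel classifier,
    and synthetic slide and cohort generators make the full pipeline
    exercisable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    grDevices,
    survival,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
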