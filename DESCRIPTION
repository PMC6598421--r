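Package: dealerscan
Title: Detection and Characterization of Drug-Dealer Posts in Tagged
    Social-Media Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end infoveillance pipeline for detecting posts that
    advertise controlled substances for sale on hashtag-driven social
    platforms. Provides JSON Lines corpus input/output with deduplication, a
    seven-step text-cleaning and encoding pipeline that separates caption
    text from hashtags, a two-branch recurrent (long short-term memory)
    neural classifier trained with Adam and validation-loss early stopping,
    three classical baselines (decision tree, random forest, support vector
    machine) over term-presence features, a 10-fold cross-validation harness
    reporting precision, recall, F1 and AUC across text/hashtag ablation
    variants, a two-loop hashtag-expansion crawler over pluggable post
    sources, and post-hoc characterization of detected posts (drug hashtag
    taxonomy with union counting, contact-channel extraction, buyer-seller
    exchange detection). A synthetic-corpus generator with planted ground
    truth makes every stage testable without platform access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    rpart,
    randomForest,
    e1071
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
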