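Package: pollentrain
Title: Weighted DenseNet Training with Flower Pollination Learning-Rate Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A training framework for four-class thyroid SPECT image
    classification. Implements a DenseNet variant whose skip connections
    carry trainable scalar weights and whose transition stages downsample
    with dilated convolution instead of pooling, a per-minibatch learning
    rate search based on the flower pollination algorithm with Levy-flight
    global moves, mixup augmentation that balances classes with soft
    labels, and a per-class one-vs-rest evaluation suite (recall,
    precision, accuracy, specificity, F1). Ships a seeded synthetic
    SPECT-like image generator so the whole pipeline can be exercised
    end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
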