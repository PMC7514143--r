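Package: ddinet
Title: Drug-Drug Interaction Relation Extraction with a Recurrent Hybrid
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts drug-drug interaction (DDI) relations from sentences that
    mention pairs of drug entities. Reads and writes the DDIExtraction-2013 XML
    dialect, performs drug blinding and rule-based negative-instance filtering,
    and classifies each candidate drug pair into one of five classes (Mechanism,
    Effect, Advice, Int, Negative) with a recurrent hybrid convolutional
    network: recurrent left/right context encoding fused with word embeddings,
    relative position embeddings, stacked typical and dilated convolutions with
    max pooling, and a softmax output trained with an improved focal loss that
    counteracts the severe class imbalance of the task. Includes micro-averaged
    precision/recall/F evaluation, a synthetic labelled corpus generator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
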