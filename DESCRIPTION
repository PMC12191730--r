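Package: abmlm
Title: Preferential CDR3 Masking for Paired Antibody Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pre-training and probing masked language models of
    natively paired antibody sequences with region-aware (preferential)
    masking. Includes a seeded simulator of paired heavy/light repertoires
    with somatic hypermutation and implanted specificity motifs, AIRR-style
    annotation handling and identity clustering, a 26-token paired-chain
    tokenizer, preferential and uniform masking-probability construction
    with a dynamic 80/10/10 corruption collator, a compact rotary-attention
    encoder with masked-language-model pre-training and region-partitioned
    validation, per-position inference accuracy with paired statistical
    comparison, frozen-base pairing and specificity classifiers, and
    gradient-based (AttCAT) token attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
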