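Package: methylm
Title: Transformer Language-Model Ensembles for DNA Methylation Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts N6-methyladenine (6mA), N4-methylcytosine (4mC) and
    5-hydroxymethylcytosine (5hmC) sites from 41-nucleotide DNA windows
    annotated with an 8-rank taxonomic lineage. Each sample is encoded as a
    sentence of overlapping 6-mer words followed by a templated lineage
    description, tokenized with a custom-trained subword tokenizer, and
    classified by an ensemble of five small transformer encoders (BERT,
    DistilBERT, ALBERT, XLNet and ELECTRA style presets) that are pretrained
    with masked-, replaced-token- or permutation-language-model objectives
    and fine-tuned in a 6mA -> 4mC -> 5hmC cascade. Includes attention-based
    interpretability (token and per-position importance, motif ranking,
    DNA-to-taxonomy attention), a genome scanning mode with a center-max
    importance filter, and a synthetic data generator with planted motifs so
    the whole pipeline runs on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
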