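Package: dmrllda
Title: Feature-Conditioned Multi-Label Supervised Topic Models for Gene
    Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Labeled latent Dirichlet allocation with a
    Dirichlet-multinomial-regression prior (DMR-LLDA) for predicting gene
    function from protein sequences.  Each gene is a document over a k-mer
    vocabulary of amino-acid blocks, each Gene Ontology term is a topic, and
    the gene's Dirichlet prior over its annotated topics is an exponential
    function of arbitrary numeric gene features (molecular weight,
    isoelectric point, hydrophilicity, ...).  Provides collapsed Gibbs
    sampling, collapsed variational Bayes (CVB) and zero-order CVB (CVB0)
    inference, fold-in prediction for unannotated genes, a full multi-label
    evaluation suite (Hamming loss, average precision, one-error,
    micro/macro F1 and three precision-recall areas), Boolean matrix
    decomposition of the label space, and a generative simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
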