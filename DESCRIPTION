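Package: kpcboost
Title: Gene Regulatory Network Inference by Kernel PCA Regression and
    Boosting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs directed transcription-factor to target-gene
    regulatory networks from steady-state expression data.  For every gene a
    greedy gradient-boosting search explores small sets of transcription
    factors; each candidate set is scored by the Jeffreys-marginalized
    likelihood of a kernel principal-component regression on the residuals,
    combined with a binomial prior over edges, and posterior edge
    probabilities are obtained by Bayesian model averaging over all explored
    models.  Includes AUROC/AUPR/best-F1 benchmarking against directed gold
    standards, probability thresholding and harmonic closeness centrality
    for downstream network analysis, a seeded simulator of sparse acyclic
    regulatory networks with nonlinear steady-state expression, readers and
    writers for delimited expression matrices and DREAM-style edge lists,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
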