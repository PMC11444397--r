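Package: rnalm
Title: Autoregressive Language Modelling and Statistical Evaluation of RNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for training byte-pair-encoding tokenizers and
    causal decoder (transformer) language models on nucleotide corpora,
    generating sequences under greedy, beam and top-k decoding, and evaluating
    generated RNA with k-mer Kullback-Leibler divergence, k-let-preserving
    shuffle controls, a weighted base-pair-maximisation folding backend,
    seeded local-alignment novelty search, and a fine-tuning pipeline for
    protein-binding RNA generation with an ablation comparison. Includes a
    synthetic-corpus module (Markov backgrounds, designed hairpins,
    motif-implanted binding sets) so the whole workflow runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
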