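Package: ngn
Title: Neural Grammar Networks for QSAR on Molecular Line Notations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits neural grammar networks (NGNs): recursive neural networks
    whose per-molecule topology is the parse tree of the molecule's SMILES or
    InChI string under a deterministic context-free grammar.  Weight layers
    are bound to grammar productions and shared across every occurrence of a
    production, so a finite library of weights processes strings of unbounded
    length; training is backpropagation through structure with momentum and
    random restarts.  Ships deterministic (LR(1)-validated) molecular
    grammars, a grammar-valid synthetic data generator, QSAR evaluation
    statistics (concordance, sensitivity, specificity, Matthews correlation,
    PRESS/q-squared, summed-residual Epsilon, exact Wilcoxon signed-rank),
    cross-validation experiment designs, and a descriptor-vector neural
    network baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
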