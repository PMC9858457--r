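Package: flicker
Title: Local Information Dynamics and Flickering Emergence in Markovian
    Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects per-transition instabilities ("flickering") of
    information-theoretic emergence in discrete Markovian systems. Provides
    labelled transition probability matrices with expected and local
    (pointwise) temporal mutual information, effective information and
    effectiveness; logic-gate coarse-grainings with the causal-emergence
    log-ratio criterion and a cross-scale incongruity census; the 16-atom
    double-redundancy lattice of the integrated information decomposition
    (PhiID) for two-element systems, solved locally per transition by
    Moebius inversion, including the causal-decoupling and downward-causation
    atoms; random-walker dynamics on weighted graphs with macro-node
    renormalization and within/between-community edge censuses; and seedable
    random-walk simulations producing per-step local emergence traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
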