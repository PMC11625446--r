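Package: midecay
Title: Mutual Information Decay Analysis of Behavioral Action Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting nonadjacent dependencies in ethogram-coded
    animal action sequences via mutual information (MI) decay. Estimates MI
    between sequence elements at increasing inter-element distances using the
    Grassberger finite-sample entropy correction, establishes a chance floor
    by sequence permutation, fits exponential, power-law and composite decay
    models by Levenberg-Marquardt least squares with AICc model selection,
    locates exponential-to-power-law transition points via log-space
    curvature, and tests dependency ranges against Markov-chain null models.
    Includes generators for synthetic sequences with known Markovian,
    hierarchical or composite ground-truth structure, and a toy nut-cracking
    corpus generator emulating the statistical shape of wild chimpanzee
    stone-tool-use data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
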