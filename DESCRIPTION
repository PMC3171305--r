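Package: raressa
Title: Rare-Event Probability Estimation for Stochastic Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie direct method and the
    Gibson-Bruck next reaction method) and importance-sampling weighted
    simulation (wSSA, wNRM) of mass-action chemical reaction networks, for
    estimating the probability that a species count first crosses a
    threshold within a time horizon.  Includes an automatic
    importance-sampling parameter-selection procedure based on partitioning
    reactions by their effect on the target species and maximizing the
    dominant term of the threshold-crossing probability, a try-and-test
    grid baseline, and an independent truncated continuous-time Markov
    chain first-passage oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
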