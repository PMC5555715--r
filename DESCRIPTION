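Package: seriar
Title: Race Models of Antisaccade Reaction Times and Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trial-level generative race models for the antisaccade task:
    the PROSA model (pro, stop, and antisaccade units) and the SERIA model
    family (stochastic early reaction, inhibition, and late action), in
    which an early GO/NO-GO race and a late decision process jointly
    produce pro- and antisaccades.  Provides exact trial likelihoods under
    four parametric increase-rate distributions, a generative simulator,
    Bayesian inference by adaptive parallel-tempered Metropolis-Hastings
    with thermodynamic-integration model evidence, fixed- and
    random-effects model and family comparison, and posterior summaries
    (late-response probabilities and response times, error-source
    decomposition, predicted reaction-time densities, reciprobit curves,
    and corrective-antisaccade predictions).
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
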