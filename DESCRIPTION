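Package: morbidmap
Title: Bayesian Geo-Additive Multinomial Modelling of Child Co-Morbidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling overlapping childhood illnesses
    (diarrhoea, fever, cough) as an eight-level co-morbidity outcome with a
    Bayesian geo-additive semi-parametric multinomial logit model.  Provides
    a synthetic DHS-style survey generator with known ground truth, survey
    ingestion and covariate recoding, descriptive chi-squared screening, a
    structured additive design builder (reference-cell dummies, P-spline
    bases with difference penalties, intrinsic CAR precision from a region
    adjacency graph), a compiled Metropolis-Hastings sampler with
    iteratively-weighted-least-squares proposals for fixed, smooth,
    structured and unstructured spatial effects, and posterior odds-ratio
    and per-region spatial-effect summaries for disease mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    splines,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    foreign
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
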