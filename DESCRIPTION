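Package: foodenv
Title: Community Food Environment Metrics and Multilevel Diet Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the community food environment of large
    cities: a synthetic-city generator producing neighbourhood polygons
    with census attributes, a named food-establishment registry and a
    nested survey sample; a grid-based point-of-interest query engine
    with cleaning and de-duplication against an abstract provider; a
    term-inventory classifier assigning establishments to eight outlet
    categories and three health groups; neighbourhood density and
    social-environment metrics with quartile-stratified tables; survey
    outcome derivation (non-daily fruit and vegetable consumption) with
    bivariate comparisons; and two-level random-intercept logistic
    regression estimated by adaptive Gauss-Hermite quadrature, with a
    progressive covariate-adjustment strategy reported as odds ratios
    with Wald confidence intervals and AIC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
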