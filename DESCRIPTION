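Package: chickgp
Title: Genomic Prediction in a Small F2 Chicken Intercross
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation of genomic selection in a small
    three-generation F2 intercross between two divergent chicken lines.
    Simulates founder lines, the cross, marker genotypes and quantitative
    traits; performs SNP quality control; builds pedigree (A) and genomic
    (G) relationship matrices; estimates variance components by AI-REML;
    predicts breeding values with pedigree BLUP, GBLUP, a Bayesian LASSO
    and a four-component Bayesian mixture model; and evaluates accuracy,
    bias, paired t-tests and statistical power under family-sample and
    random-sample 4-fold cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
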