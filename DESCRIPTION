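Package: ibdscreen
Title: Identity-by-Descent Segment Detection from Imputed Genotype
    Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects identity-by-descent (IBD) segments between pairs of
    diploid individuals from phased, imputed genotype probabilities of the
    kind produced by low-coverage ancient-DNA imputation pipelines. A
    five-state hidden Markov model with continuous-rate transitions along
    the genetic map and a haploid-dosage emission model yields per-site
    posteriors, which are postprocessed (thresholding, gap merging, SNP
    density filtering, optional region masks) into segment calls. Includes
    batch all-pairs screening with per-pair sharing summaries and
    relative-class annotation, a mosaic-haplotype simulator with copied-in
    IBD and aDNA-like genotype-probability noise, a pedigree meiosis
    simulator for relationship expectations, and evaluation utilities
    (power, false-positive rates, length bias, constant-Ne sharing
    expectations, parameter grid search).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
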