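Package: allomorph
Title: Allometric Scaling and Diversification of Avian Hindlimb Segment Masses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Standardized major axis (model II) regression with isometry,
    common-slope, and elevation tests; phylogenetic generalized least
    squares; maximum-likelihood fitting of Pagel's lambda and delta
    branch-length-transform models of trait evolution; and parametric
    Monte Carlo (bootstrap) model comparison. Bundles a species-mean
    morphometric table of hindlimb segment masses for 38 neognath bird
    species and a synthetic-data generator (Yule trees, trait evolution,
    allometric tables) so the whole analysis pipeline is testable with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
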