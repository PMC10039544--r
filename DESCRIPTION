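Package: multinet
Title: Multi-Level Weighted Gene Co-Expression Networks for Two-Trait Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs weighted gene co-expression networks at the three
    design levels of a two-trait expression dataset (the combined network,
    one network per level of the primary trait, and one per level of the
    secondary trait), maps modules between networks by hypergeometric
    member overlap, associates module eigengenes with the two traits by
    factorial ANOVA or PERMANOVA, tests trait-specific module preservation
    against a size-matched phenotype-permutation null, screens gene pairs
    for differential co-expression between conditions with the Fisher
    r-to-z test, and traces module dynamics (gene flow and topological
    dispersion) across condition-specific networks. A synthetic two-trait
    data generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, car, vegan, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
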