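Package: minkpat
Title: Minkowski-Functional Quantification of Egg Pattern Mimicry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Threshold-sweep Minkowski functionals (perimeter, area and
    Euler characteristic) for quantifying biological surface patterns such
    as the scribbled markings of bird eggs. Binary images are obtained at
    80 intensity thresholds and the per-level perimeter P, area A and Euler
    characteristic are integrated into the summary statistics Sigma(P^2/A)
    and Sigma(Euler), which separate long thin curvilinear markings
    ("scribbles") from compact blotches. Includes seeded generators for
    synthetic scribble and blotch patterns and a painting manipulation,
    simplified granularity-style pattern traits, flexible discriminant
    analysis by optimal scoring with principal-component reduction, and
    receiver-response statistics (binomial logistic regression of rejection
    on treatment and matched-pairs t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
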