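Package: osteoprofile
Title: Biological Profiling of Fragmentary Human Long-Bone Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for reconstructing biological profiles from
    fragmentary skeletal assemblages of Pleistocene hominins. Provides a
    resampling test for demographic composition bias (Monte Carlo draws from
    mortality-structured reference populations, with exact multinomial and
    multivariate hypergeometric counterparts), osteometric stature
    reconstruction from long-bone lengths with femur-priority rules and
    Welch group comparison, cross-sectional geometry of cortical bone rings
    (areas, second moments of area, polar section modulus), and
    landmark-based geometric morphometrics of diaphyseal cross-sectional
    shape (equiangular semilandmarks, generalized Procrustes analysis, PCA,
    group confidence ellipses, wireframes). A synthetic-data module
    generates mortality-structured populations, biased assemblages and
    parametric cortical-ring sections with closed-form oracles so the whole
    pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
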