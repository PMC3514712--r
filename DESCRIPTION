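Package: funnelmorph
Title: Geometric Morphometrics of Developmental Axes in Cranial Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Landmark-based tools for asking whether discrete developmental
    perturbations (brain growth, chondrocranial growth, overall growth)
    correspond to axes of covariation in normal cranial shape. Provides
    Generalized Procrustes Analysis with tangent projection, pooled
    within-sex multivariate regression of shape on size predictors,
    mutant-versus-wildtype mean-shape contrasts with Procrustes distances,
    permutation inference, thin-plate spline deformation grids, TPS/CSV
    landmark input and output, and a seeded synthetic landmark-data
    generator for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
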