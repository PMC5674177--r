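Package: wingmorph
Title: Landmark-Based Geometric Morphometrics for Taxonomic Assignment of Insect Wings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for placing specimens of unknown taxonomic affinity from
    two-dimensional landmark configurations of wing venation. Implements
    generalized (GLS) Procrustes superimposition with tangent-space projection
    and an adequacy check, linear discriminant analysis of tangent coordinates
    with leave-one-out cross-validated hit-ratios, a posteriori assignment of
    unknowns by posterior probability and Mahalanobis distance, principal
    component ordination with projection of the unknown, TPS-format input and
    output, and a hierarchical assignment cascade over nested reference
    datasets. Includes a synthetic landmark-data generator emulating nested
    taxonomic structure for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
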