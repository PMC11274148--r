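Package: dissectwall
Title: Hemodynamic and Geometric Assessment of Dissected Aortas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the hemodynamic and geometric characterization of
    residual type B aortic dissection. Generates idealized dissected-aorta
    surface meshes with true/false lumen and entry-tear labeling, drives them
    with an analytic Womersley pulsatile-flow surrogate, and computes the
    standard wall-shear-stress descriptors (time-averaged wall shear stress,
    oscillatory shear index, relative residence time), lumen geometry metrics
    (tortuosity, true-lumen to descending-aorta area ratio, tear area, growth
    classification), flow partition and inter-lumen pressure differentials,
    mesh-sensitivity and time-step utilities, and two-group cohort statistics
    with normality-gated tests. A seeded synthetic-cohort generator emulates a
    22-patient residual dissection population so every pipeline stage is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
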