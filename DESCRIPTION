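Package: stemopt
Title: Design Optimization of Cemented Femoral Hip Stems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric design and optimization of the stem of a cemented
    total hip prosthesis. Provides superellipse-based parametric stem
    geometry with spline lofting and STL export, a composite-beam
    structural surrogate of the femur-cement-implant assembly under a
    walking load case, stress-life fatigue assessment of the cement
    mantle (Goodman mean-stress correction, S-N life, binary nodal
    damage), quantification of bone stress shielding, and a two-level
    Taguchi orthogonal-array optimizer with variance-weighted
    farthest-point probabilistic restarts that minimizes a combined
    normalized objective. Supports homogeneous titanium-alloy and
    layered functionally graded stem materials, and import of externally
    computed stress fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
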