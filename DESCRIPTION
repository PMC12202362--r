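Package: vesselmetrics
Title: Zone-Wise Vessel Morphometry for En-Face OCTA Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal vessel morphology on en-face optical
    coherence tomography angiography (OCTA) artery/vein label maps of
    3x3 mm macular scans. Partitions the field into the fovea and four
    parafoveal quadrants, reduces vessel masks to centerline tracks, and
    computes vessel density, vessel diameter index, vessel length
    fraction, box-counting fractal dimension, and a tortuosity family
    (mean direction angle change, arc length, and total squared curvature
    normalized by arc or chord length) per zone and vessel class. Includes
    a parametric vessel-phantom generator with analytically known
    geometry, a cohort simulator with injectable group effects, and the
    group-comparison protocol used in OCTA studies (Kolmogorov-Smirnov
    normality gate, one-way ANOVA with LSD or Tamhane T2 post hoc, or
    Kruskal-Wallis, plus chi-square tests for count data).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils,
    car,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
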