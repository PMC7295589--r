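Package: cellwalk
Title: Quantitative Analysis of Glucocorticoid Effects on Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying drug effects on single-cell migration and
    protein-protein interaction from live-cell imaging readouts. Implements
    trajectory kinematics (step lengths, path-length displacement, rose-plot
    transforms, cumulative-distance matrices), alpha-stable (Levy) modelling
    of pooled step lengths with a resampling protocol for parameter
    uncertainty, fluorescence cross-correlation spectroscopy (FCCS) curve
    fitting with amplitude-to-concentration conversion and in vivo
    dissociation-constant estimation, vehicle-anchored tertile analysis of
    microtubule growth speeds, an earliest-significant-time rank-sum scan,
    and seeded synthetic-data generators so the whole pipeline is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
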