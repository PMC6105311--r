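Package: aortamap
Title: Unwrapping Tubular Vessels into Calibrated 2D Cartographies
Version: 0.1.0
Authors@R:
    person("Aorta", "Map Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic segmentation of a roughly cylindrical fluorescent
    vessel (the zebrafish dorsal aorta) by crown-constrained circle fitting,
    unwrapping of the fitted tube into isotropically calibrated planar 2D-maps,
    quantification of oscillatory apical-constriction kinetics from paired
    junction-spot tracks (double sliding-average smoothing, closing speed,
    prominence-filtered local minima, cycle durations), and cell morphometry
    and classification (floor/roof/medio-lateral partition, neighbour counts)
    on the maps. Includes a ground-truthed synthetic phantom generator for
    cylindrical vessel volumes with a Voronoi membrane tessellation and for
    oscillatory spot-track pairs, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    deldir,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
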