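Package: vcmaps
Title: Coordinated Optimization of Visual Cortical Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models of the joint pattern formation of orientation-preference
    and ocular-dominance columns in primary visual cortex: coupled
    Swift-Hohenberg gradient-descent dynamics of a complex and a real order
    parameter field under symmetry-classified inter-map coupling energies,
    the coupled amplitude equations near threshold with closed-form
    stationary planforms (stripes, rhombic and hexagonal pinwheel crystals,
    orientation-scotoma states) and numerical linear stability, the
    ocular-dominance subsystem (bias-shift mapping, triad-resonance
    amplitude equations, stability borders, contralateral fractions), map
    geometry statistics (pinwheel detection and topological charges,
    critical-point classification, intersection angles, orientation
    histograms), and phase-diagram assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, grDevices, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
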