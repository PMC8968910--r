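Package: magnegel
Title: Magnetophoretic Alignment Simulation and Fiber Micrograph Quantification
Version: 0.1.0
Authors@R: person("Magnegel", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying magnetic-nanoparticle (MNP) mediated alignment
    of collagen hydrogels between facing permanent magnets. Provides analytic
    magnetostatics for a two-cuboid-magnet device (field, field gradient, and
    remanence calibration), an overdamped magnetophoretic particle-tracing
    simulation with Stokes drag and directionality-of-motion statistics,
    Fourier-spectrum directionality histograms of grayscale micrographs with
    Gaussian fitting and anisotropy classification, a thresholded run-length
    segmentation statistic on half-height intensity transects, seeded synthetic
    micrograph generators with ground truth for parameter-recovery testing, and
    a reproducible experiment pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    withr,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
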