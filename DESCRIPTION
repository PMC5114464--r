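Package: corowave
Title: Wave Reflection and Scaling Laws at Coronary Bifurcations
Version: 0.1.0
Authors@R: person("Coronary", "Waves", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links vascular scaling laws (Murray, Huo-Kassab) to pulse-wave
    reflection at coronary bifurcations. Provides a rooted-tree data model for
    vascular networks, closed-form area-ratio/symmetry-ratio relations under
    the well-matchedness condition, a Womersley pulsatile-flow extension with
    complex characteristic impedance, three pulse-wave-speed parametrizations
    (uniform speed, uniform wall stiffness, empirical exponential wall law),
    a synthetic coronary-tree generator emulating measured branching
    statistics, and an analysis pipeline for clustering bifurcations, fitting
    scaling exponents, and summarizing reflection-coefficient distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
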