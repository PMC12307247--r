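Package: trunkgait
Title: Trunk-Accelerometry and Plantar-Pressure Gait Analysis for Lower-Limb Amputees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for amputee gait assessed with a single trunk-mounted
    (S1) inertial sensor and a baropodometric platform. Segments anteroposterior
    trunk acceleration into per-limb gait cycles, time-normalizes and averages them,
    and computes the correlation-based gait symmetry index, the single-support
    propulsion index, the stance/swing quality index, body-weight distribution from
    standing plantar-pressure frames, and spatiotemporal parameters (cadence,
    velocity, stride length, two-minute walk distance). Includes a synthetic gait
    and standing-pressure simulator with exact ground truth for validation, and a
    normality-gated two-group comparison (Shapiro-Wilk gate, Student t or
    Wilcoxon rank-sum) for cohort reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
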