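Package: sgmotion
Title: Self-Gated Cardiac and Respiratory Motion Extraction for Free-Running MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for extracting cardiac and respiratory motion signals from
    the superior-inferior (SI) projections of free-running radial cardiac MRI
    acquisitions. Implements principal component analysis, second-order blind
    identification (SOBI) by joint diagonalization of time-lagged covariance
    matrices, and FastICA for blind source separation; automated spectral
    component selection; zero-crossing cardiac trigger detection; ECG trigger
    cleaning, alignment, and the interval-standard-deviation precision metric;
    respiratory amplitude and cardiac phase binning; a desk-scale motion-resolved
    compressed-sensing reconstruction solved by ADMM; and a sigmoid-fit edge
    rise-distance sharpness metric. A seeded synthetic-data module generates SI
    projection stacks, ECG trigger trains, and dynamic phantoms with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
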