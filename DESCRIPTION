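Package: streamloop
Title: Streaming Analysis and Closed-Loop Adaptive Design for Neural Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An actor-based streaming pipeline framework for adaptive
    neuroscience experiments, together with the online estimators that run
    inside it: frame-level image preprocessing (Otsu binarization,
    Sorensen-Dice plane alignment, ROI trace extraction, spike binning and
    direction-selectivity tuning), streaming subspace tracking (proSVD),
    streaming ridge regression, a sliding-window stochastic-gradient
    linear-nonlinear-Poisson model with functional connectivity, a streaming
    Gaussian-mixture hidden Markov model for trajectory prediction, and
    closed-loop Bayesian optimization of visual stimuli on a toroidal grid
    with adaptive photostimulation target selection. Synthetic-data
    generators with ground truth make every stage testable end to end
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
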