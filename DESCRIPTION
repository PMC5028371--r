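Package: peepstep
Title: Lung and Expanding Chest Wall Bench Model for PEEP-Step Estimation
    of Transpulmonary Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter simulation of a physical respiratory-system
    bench model: parallel elastic test lungs recoil inside an evacuated
    pleural gas space that is coupled, through a water-filled container and
    a resistive valve, to a plastic abdominal sack, so that the rib-cage
    spring-out force is reproduced hydraulically.  The package drives the
    model with a volume-controlled ventilator, runs PEEP-step protocols,
    and implements the full measurement pipeline used at the bench: breath
    segmentation of 100 Hz waveforms, PEEP-change detection, the 15-breath
    cumulative change in end-expiratory lung volume with 5-breath flow
    offset compensation, tidal and end-expiratory elastance partitioning,
    and the regression of measured against elastance-predicted lung volume
    changes.  The central result it reproduces is that end-expiratory
    pleural pressure stays near its baseline after PEEP inflation, so lung
    elastance can be estimated as the PEEP change divided by the
    end-expiratory volume change, without esophageal manometry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
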