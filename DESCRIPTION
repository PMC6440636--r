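Package: vrsoundloc
Title: Binaural Cue and Pointing-Response Analysis for Sound Localization in Virtual Reality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how a head-mounted display (HMD) perturbs
    acoustic sound-localization cues and how those perturbations, together
    with the available visual information, affect pointing responses in a
    loudspeaker-based virtual sound environment. Implements extraction of
    binaural cue errors (spectral difference, interaural level difference and
    interaural time difference) from paired binaural impulse responses using
    an ERB-spaced gammatone filterbank and minimum-phase cross-correlation
    delay estimation; the three-step rigid calibration of a virtual
    environment onto tracked real-world reference points with residual
    monitoring; and the behavioral pipeline of handedness mirroring,
    pointing-bias estimation and correction, outlier screening and
    signed/absolute angular-error summaries. A synthetic-data module
    generates spherical-head binaural impulse responses, a parametric HMD
    perturbation, pink-noise stimuli and simulated subject responses so that
    every stage of the pipeline can be exercised without measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
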