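Package: digikit
Title: EEG Electrode Digitization with 6-DOF Tracked Styluses
Version: 0.1.0
Authors@R:
    person("digikit", "developers", email = "digikit@example.org",
           role = c("aut", "cre"))
Description: A hardware-independent engine for digitizing EEG electrode
    positions with a 6-DOF tracked stylus: pivot (endpoint) calibration of
    the stylus tip by spread minimization over rigid poses, stability-gated
    sampling of timestamped pose streams, head-movement compensation using
    one or two head trackers with slip (mismatch) detection, montage and
    fiducial session management, rigid point-set alignment (Kabsch) and
    localization-error statistics (per-electrode Euclidean error, RMSE,
    Welch's t-test).  Includes a synthetic 6-DOF pose simulator providing
    ground truth for every stage, and a command-line interface for replay
    digitization and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
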