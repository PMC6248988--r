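# digikit

EEG electrode **digitization** with 6-DOF tracked styluses, as a
hardware-independent R library and command-line tool.

Source imaging of EEG needs to know where each electrode actually sat on a
subject's head. Consumer VR tracking (a tracked controller used as a stylus,
plus trackers strapped to the head) can measure those positions at a
fraction of the cost of dedicated digitizers. `digikit` re-implements the
processing engine such a system needs, decoupled from any live device:

* **Pivot (endpoint) calibration** — estimate the stylus-tip offset
  $\vec{x}_c$ in the controller frame from $N$ poses $\{T_i\}$ sharing one
  fixed physical tip location, by minimizing the spread of the implied
  global tip positions
  $\sum_i \bigl| T_i(\vec{x}_0+\vec{x}_c) - \tfrac1N\sum_j T_j(\vec{x}_0+\vec{x}_c) \bigr|^2$,
  with a closed-form linear pivot solve kept as an independent oracle.
  Calibration quality is the maximum deviation of the implied tips from
  their mean (mm).
* **Stability-gated sampling** — a triggered measurement is the mean
  endpoint position over a trailing 0.5-s window, accepted only if the
  endpoint stayed within 1 mm of the 1.0-s window mean (rejects
  post-movement transients).
* **Head-movement compensation** — measurements are expressed relative to
  one or two head trackers; with two trackers, slip of one tracker on the
  head is detected from the change in their relative transform.
* **Sessions** — montage import (`.sfp`, `.elc`, CSV), repeated-fiducial
  averaging with spread checks, head-shape points, JSON persistence, STL
  and OFF mesh parsing.
* **Evaluation** — rigid (Kabsch) alignment by fiducials or by electrodes,
  per-electrode Euclidean error, RMSE, Welch's two-tailed t-test, and the
  reference-selection rule (first dataset unless a later one has fewer
  rejected electrodes).
* **Simulator** — a synthetic 6-DOF pose generator (ellipsoidal head,
  128-electrode radial layout at 18–25 mm spacing, rigid head motion,
  band-limited jitter, quasi-static tracking distortion, post-movement
  transients) providing exact ground truth for every stage.

## Worked example

```r
library(digikit)

# calibrate the stylus endpoint from 10 simulated poses (27-mm stub)
cal <- simulate_calibration(c(0, 0, -27), n_poses = 10,
                            rotation_spread_deg = 90, seed = 1)
calibrate_endpoint(cal)
#> calibration_result: endpoint (0.000, -0.000, -27.000) mm, max deviation 0.0000 mm over 10 poses

# simulate a noisy two-tracker session and evaluate it against ground truth
cfg <- scenario_config(jitter_sigma = 0.4, bias_sigma = 1.5,
                       tracker_bias_sigma = 0.5, transient_mm = 2,
                       head_drift_mm = 5, seed = 9901)
truth <- generate_layout(cfg)
sim <- simulate_session(truth, cfg)
ses <- replay_digitize(sim$stream, montage(rownames(truth$electrodes)),
                       cfg$endpoint_truth, tracker_ids = names(truth$mounts))
evaluate_dataset(ses, truth_session(truth), mode = "electrodes")
#> alignment_result (electrodes): RMSE 2.783 mm, max 5.320 mm over 113 electrodes
```

The RMSE is the root-mean-square of the per-electrode Euclidean distances
to the reference after a single rigid alignment; ~2.8 mm is the regime this
class of hardware shows in practice (its stated-world noise model predicts
~2.6 mm). Electrodes whose measurement failed the 1-mm stability gate are
excluded, which is why 113 of 128 electrodes enter the error map here.

The same workflows are available from the shell via `exec/digikit`:

```sh
digikit simulate --config scenario.yaml --out-stream stream.jsonl --out-truth truth.json
digikit calibrate --poses cal.jsonl --out cal.json
digikit digitize --replay stream.jsonl --montage cap.csv --endpoint cal.json \
        --trackers tracker1,tracker2 --out session.json
digikit align --test session.json --ref reference.json --mode electrodes --out result.json
digikit evaluate --sessions "sessions/*.json" --report report.csv
```

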