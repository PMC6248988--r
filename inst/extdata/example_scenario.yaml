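# Example digitization scenario for `digikit simulate` (synthetic; all
# quantities in mm / s / Hz).  Noise levels describe a plausible consumer-VR
# tracking session; set them to 0 for an exactly recoverable run.
n_electrodes: 128
jitter_sigma: 0.4
bias_sigma: 1.5
tracker_bias_sigma: 0.5
transient_mm: 2
head_drift_mm: 5
n_trackers: 2
fiducial_repeats: 2
seed: 1
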