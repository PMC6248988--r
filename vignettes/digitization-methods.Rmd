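---
title: "Models and methods behind digikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind digikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`digikit` processes 6-DOF pose streams from a tracked stylus (and optional
head trackers) into labeled EEG electrode positions, and evaluates the
resulting digitizations. This vignette is the package's own account of its
models, numerical choices, and the limits of what its tests establish.

## Coordinate conventions

Every pose is a rigid transform $T = (R, t)$ mapping device-local to global
coordinates, $p \mapsto Rp + t$, with $R$ orthonormal and $\det R = +1$.
All lengths are millimeters; meter-native streams must be converted at
ingestion (factor 1000). Frames are treated as abstract and right-handed —
replayed data from a real tracking system must declare its own axis
convention; nothing downstream depends on it because all error measures are
invariant to a global rigid change of frame. Rotations are stored as
matrices throughout: orientations are never averaged (only endpoint
*positions* are), so no quaternion-mean machinery is needed. Construction
validates rigidity to $10^{-9}$; matrices off by at most $10^{-6}$
(accumulated round-off) are projected to the nearest rotation via SVD and
flagged, anything worse is rejected.

## Endpoint (pivot) calibration

The stylus tip is a physical point $\vec{x}_c$ fixed in the controller
frame. Holding the tip at one fixed location in space and rotating the
controller through $N$ poses $\{T_i\}$, the implied global tip positions
$\vec{x}_{g,i} = R_i \vec{x}_c + t_i$ should coincide; the calibration
estimate minimizes their spread,

$$\hat{x}_c = \arg\min_{\vec{x}_c} \sum_{i=1}^{N}
\Bigl| \vec{x}_{g,i} - \tfrac{1}{N}\sum_j \vec{x}_{g,j} \Bigr|^2 ,
\qquad |\vec{x}_c| \le b .$$

Two facts shape the implementation:

* Writing $D_i = R_i - \bar R$, the objective is the convex quadratic
  $\sum_i |D_i \vec{x}_c + (t_i - \bar t)|^2$. Eliminating the unknown
  fixed point from the classical stacked pivot system
  $R_i \vec{x}_c - p = -t_i$ yields exactly this quadratic, so the linear
  least-squares pivot solve *is* the unconstrained spread minimizer. The
  package keeps both routes: `linear_pivot_oracle()` (closed form, also the
  initialization) and `calibrate_endpoint()` (bounded quasi-Newton
  refinement, tolerance $10^{-9}$, at most 500 iterations). Tests require
  them to agree to $10^{-6}$ mm on noiseless sets and the refined objective
  never to exceed the oracle's.
* The norm bound $b$ (default 200 mm — physical stylus stubs are
  centimeters, e.g. a 27-mm connector stub) is rarely active; when it is,
  the constrained minimum of the quadratic on the ball is found by
  bisection on the Lagrange multiplier.

**Identifiability.** If all rotations are equal (or differ only by spins
about a single axis through the tip), $\vec{x}_c$ is not identifiable along
the deficient direction. The guard is the smallest singular value of the
stacked $(R_i - \bar R)$ system; below $10^{-3}$ the set is flagged
degenerate and the solver refuses (naming the deficient device-frame
direction) unless explicitly overridden.

**Quality metric.** The reported calibration quality is
$\max_i |\vec{x}_{g,i} - \bar{x}_g|$ — the *unsquared* maximum deviation
from the mean, in mm, so it reads directly as a distance. (The squared form
of the same term is what the optimizer monitors.)

## Stability-gated sampling

A trigger at time $t_0$ produces a measurement from the trailing windows:

* position = mean endpoint position over $[t_0 - 0.5\,\mathrm{s},\, t_0]$
  (suppresses high-frequency jitter);
* stability = maximum deviation of the samples in
  $[t_0 - 1.0\,\mathrm{s},\, t_0]$ from that window's own mean; the sample
  is **valid** iff stability $\le 1$ mm (rejects post-movement settling
  error, which can persist for seconds).

Deviation-from-windowed-mean was chosen as the stability statistic because
it is symmetric, order-independent, and reduces to the intended behavior
for both drift and steps. Both windows end *at* the trigger: the
measurement happens when the operator confirms placement. Windows need at
least 3 samples and full coverage, else an insufficient-data error. A
consequence worth knowing: with a transient of amplitude $A$ and decay time
$\tau$ after arrival at a target, the gate clears only once
$A e^{-t/\tau}$'s in-window excursion drops under threshold — for
$A = 5$ mm, $\tau = 0.4$ s that is ~1.5 s after arrival, *not* at the end
of a 1.2-s dwell; the tests assert this computed behavior.

## Head-movement compensation

With trackers rigidly attached to the head, a head-fixed point has constant
coordinates in each tracker's frame: per-tracker coordinates are
$P_k(t)^{-1} \vec{x}_g$. With two trackers the per-tracker coordinates are
re-expressed in a single session frame — tracker 1's pose at session start
— and averaged; averaging in a common frame is the natural combination rule
when both trackers are equally trusted. When head tracking is enabled, the
*windowing is done on the compensated series* (the frame in which the point
is stationary), so head motion during a dwell does not trip the gate.
Cross-device time alignment uses the nearest sample within 50 ms, no
interpolation (streams are densely sampled, ≥ 60 Hz).

**Slip detection.** The relative transform
$P_1(t)^{-1} \circ P_2(t)$ is constant while both trackers stay put. The
mismatch magnitude is the largest displacement of a probe set (tracker-2
origin plus three 100-mm axis points) under the current versus the
session-initial relative transform; the default 3-mm threshold at the
100-mm lever arm is comparable to the overall error scale of this class of
hardware (~2–4 mm RMSE). Single-tracker sessions report "not applicable"
rather than erroring.

**Replay semantics.** Replay binds the $i$-th trigger to the $i$-th
planned target (fiducials in declared order and repeats, then electrodes in
montage order, then optional fiducial re-measurements as head-shape
points). A gate-invalid electrode sample is kept but flagged invalid and
excluded from exports and evaluation — in interactive use the operator
would re-measure on cue, which a pre-recorded stream cannot emulate;
skipping to the next trigger instead would silently mislabel every
subsequent electrode.

## Alignment and error statistics

Rigid alignment uses the cross-covariance SVD (Kabsch) with determinant
correction: $H = X^\top Y$, $H = USV^\top$,
$R = V\,\mathrm{diag}(1,1,\det(VU^\top))\,U^\top$, which also resolves
degenerate-spectrum ties; no scaling, no affine option. At least 3
non-collinear pairs are required. Evaluation aligns a test session to a
reference by *fiducials* (aggregated positions — the co-registration
workflow) or by *electrodes* (direct least-squares over the shared set),
then always reports per-**electrode** Euclidean errors, their RMSE and
maximum, over the intersection of usable (non-rejected, gate-valid)
electrodes. Electrode-mode RMSE can therefore never exceed fiducial-mode
RMSE on the same error set, a property the tests verify on random pairs,
along with equivalence to an SVD-free rotation-grid + refinement oracle on
small instances.

Group comparisons between digitization conditions use Welch's two-tailed
unequal-variance t-test with Satterthwaite degrees of freedom, computed by
formula (no multiplicity correction); identical zero-variance groups give
the conventional $t = 0$, $p = 1$, flagged degenerate. The reference
dataset among repeated candidates is the first, unless a later candidate
has strictly fewer rejected electrodes, in which case the later candidate
with the fewest rejections (earliest on ties) is chosen — the
last-resort generalization of the stated pairwise rule.

## The simulator: what it emulates, and what not

The generator builds an ellipsoidal head (semi-axes 80 × 95 × 90 mm; x
right, y anterior, z up) with `n` electrodes placed by a Fibonacci spiral
on the surface above $z/c = -0.2$, labeled in top-down ring order (A1..D32
at $n=128$). The head size was fixed once so that the 128-electrode layout
reproduces the observed 18–25 mm median inter-electrode spacing
(~20.5 mm) while remaining an anthropometrically plausible adult head;
for other $n$ the feasibility band scales as $\sqrt{128/n}$ and is not
enforced below $n = 32$. Fiducials sit at plausible nasion/preauricular
landmarks on the surface; two tracker mounts sit on the forehead. Head
motion is a single constant-velocity rigid segment (translation plus slow
rotation about z) — no subject-motion statistics exist to justify anything
richer.

**Noise model and its rationale.** Translation noise is the sum of three
phenomenological components, each with an explicit reason to exist:

1. *Band-limited jitter*: zero-mean AR(1) per component, stationary sd
   `jitter_sigma`, correlation time 1.0 s. White (iid) noise at the jitter
   levels this class of hardware tolerates (0.3–0.5 mm) would exceed the
   1-mm stability gate almost surely within a 90-sample window
   ($\max$ of 90 iid draws ≈ 3.4 sd), i.e. the device's own empirically
   tuned gate would reject everything — so the jitter the gate was tuned
   against must be temporally correlated. The sd calibration is testable
   exactly: within a dwell, successive emitted differences are AR(1)
   increments with variance $2\sigma^2(1-\rho)$, and the increment-based
   estimate must land within 5% of the configured sd.
2. *Quasi-static distortion*: a per-dwell constant offset (sd `bias_sigma`
   for the controller, `tracker_bias_sigma` for trackers). Beacon-based
   optical tracking has pose-dependent static error at the mm scale; this
   is the component that survives the 0.5-s average and dominates final
   localization error. Error budget: a per-component bias sd of
   $\sigma_b$ yields per-electrode errors of magnitude
   $\approx \sigma_b\sqrt{3}$ and hence RMSE $\approx \sigma_b\sqrt{3}$
   after alignment; $\sigma_b = 1.5$ mm predicts ~2.6 mm, inside the
   1–5 mm regime typical of consumer-VR digitization (measured ~2.8 mm in
   the reference noisy scenario).
3. *Post-movement transient*: an exponentially decaying burst
   ($A e^{-t/\tau}$, random direction) after each transit, the phenomenon
   the 1.0-s stability gate exists to reject.

Noise defaults are **zero** so the base scenario is exactly recoverable;
noisy scenarios state their levels explicitly. All randomness derives from
the scenario seed: identical seed + config gives bit-identical streams.

**What a green test does not establish.** The simulator is
phenomenological: no optical sweep timing, no occlusion geometry, no
rotational jitter (jitter is translational only, so ground-truth error
accounting stays analytic), no IMU fusion dynamics, and electrode targets
are mathematical points rather than 2-mm printed label dots. Passing the
end-to-end bracket (1–5 mm noisy RMSE) shows the pipeline's error
*propagation* is sound under a stated noise budget, not that any specific
hardware achieves a specific accuracy; the study-scale accuracies of real
systems on real heads are hardware measurements that desk-scale simulation
cannot reproduce, which is why acceptance is property-based.

## Numerical and interface choices

* Pose streams are JSON-lines (`{t, device, T[16]}` row-major, bottom row
  0,0,0,1; triggers as `{t, device, event:"trigger"}`), written with 17
  significant digits so write-then-read round-trips bit-exactly.
* Session files are JSON with a schema version and explicit `"mm"` unit
  declaration; positions round-trip to better than $10^{-12}$ mm.
* Montage dialects: `.sfp` (label x y z, assumed mm), ASA-style `.elc`
  (honors `UnitPosition`), plain CSV; recognized fiducial labels (nasion /
  nz / fidnz, lpa / fidt9, rpa / fidt10) are routed to the fiducial set
  rather than the montage. Which formats the original ecosystem accepted
  is not enumerated anywhere; these three cover the common cases.
  `.fsmesh` is out of scope; STL (ASCII and binary) and OFF meshes are
  parsed and bounding-box validated only — no rendering.
* Repeated fiducials aggregate by the mean; the spread metric is the
  maximum pairwise distance, warning above 3 mm. Whether historical
  practice aligned by aggregated or first-measurement fiducials is
  unstated; aggregation matches the averaging rationale for repeats.
* The CLI is a single executable with subcommands; every run writes a
  `<output>.run.json` parameter record (config + seed) sufficient to
  reproduce it exactly. Exit codes distinguish usage (2), missing file
  (3), schema/parse (4) and computation (5) failures.

## Known limitations

Outlier-robust (RANSAC-style) calibration and anisotropic noise modeling
are deliberately absent; electrode rejection is manual (plus an advisory
flag), as identifying operator swaps is a human inspection step; the
simulator's noise magnitudes for any particular tracking product are
assumptions to be overridden per scenario, not measurements.
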