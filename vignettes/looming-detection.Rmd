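---
title: "Motion-contour-guided looming detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-contour-guided looming detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`loomcontour` implements a bio-inspired visual collision detector with two
synergistic pathways modelled on the insect optic lobe, fused by a
motion-flux statistic along the moving target's contour.

**Motion-sensitive pathway.** Each luminance frame `I(x, y, t)` in `[0, 1]`
is smoothed by a Gaussian ommatidium profile (`sigma1 = 1` px), band-passed
in time by a Large Monopolar Cell filter — the difference of two unit-mass
Gamma kernels, `H = Gamma(2, 3) - Gamma(6, 9)` (time constants in frames;
one discrete step = one frame) — and half-wave rectified into ON (`Tm3`) and
OFF (`Tm2`) channels whose Gamma-delayed counterparts (`Mi1`, `Tm1`,
`Gamma(25, 30)`) provide the temporal memory for Hassenstein–Reichardt
correlation. A lobula-plate correlator bank multiplies the instantaneous
channel at each pixel with the delayed channel of a neighbour at distance
`beta` (the published set `{2, 4, ..., 18}` px) along each of 8 directions
(45° steps; the direction count is a design choice — the lobula plate's four
cardinal layers extended with diagonals). Per pixel and per distance, the
best direction is selected; the circular mean over distances gives the local
motion direction, and the response *vector* across distances is the
population code from which speed is decoded against a calibrated tuning
table.

**Contour-sensitive pathway.** The retina output also feeds a Gaussian
inverse-gradient edge map `g = exp(-|grad P|^2 / (2 sigma2^2))`
(`sigma2 = 7` on a 0–255 intensity scale), rescaled to maximum 1. A geodesic
active contour is initialised from the dominant motion region and evolved as
a narrow-band level set under `phi_t = g K |grad phi| + grad g . grad phi`
(curvature smoothing plus edge-guided advection, no balloon term), with
upwind advection, central-difference curvature, periodic redistancing, and a
stop rule of 300 iterations or mean front displacement below 0.1 px per 10
sweeps. The zero level set is extracted by marching squares as a closed
sub-pixel polyline with outward normals.

**Collision perception.** The motion flux
`Phi(t) = sum (U . n) dl` integrates the decoded outward-normal velocity
along the contour. Expansion accumulates positive flux; translation cancels
around a closed curve (divergence theorem); contraction is negative. The
alarm examines the flux increments `DeltaPhi(t)` over a window of
`Ncon + 1 = 5` frames against the critical expansion threshold
`xi_th = 3.5` px²/frame.

## Temporal units and filter warm-up

All Gamma time constants are interpreted in frames. Discrete kernels are
sampled at unit steps, truncated where taps fall below `1e-3` of the peak,
and renormalised to unit sum, so the lamina difference kernel has exactly
zero DC and any static scene yields an identically zero channel set. Alarms
are suppressed for the longest kernel support plus `Ncon` frames (63 with
the defaults) while the filters fill.

## The decision rule: persistence, not a windowed sum

Two readings of the alarm rule coexist: a windowed *sum* of flux increments
exceeding `xi_th`, and *persistence* — every increment in the window
individually exceeding `xi_th` ("continuously exceed ... for a persistent
window"). The sum telescopes to `Phi(t) - Phi(t - Ncon - 1)`, which makes it
fire on any transient flux swing (deforming or translating targets produce
swings of tens of px²/frame) and makes a *larger* window fire *earlier* on an
accelerating flux — the opposite of the observed behaviour that larger
`Ncon` delays the response and shrinks the safety margin. The persistence
rule reproduces both behaviours and is robust to single-frame perturbations,
so it is the default (`decision_params(rule = "persistence")`); the windowed
sum remains available (`rule = "windowed_sum"`) for sensitivity studies.

## Speed decoding and the sensitive range

With the published delay constant `tau3 = 30` frames, a correlator at
distance `beta` prefers speeds near `beta / tau3`, i.e. 0.067–0.6 px/frame
across the distance set; the delay kernel has negligible mass below ~12
frames of lag, so stimuli crossing a correlation span in under a frame
produce no usable correlation. Calibration on drifting-edge stimuli confirms
that response vectors above ~0.9 px/frame fall below the decoding floor.
The default candidate grid is therefore 0.05–0.8 px/frame (0.025 steps up to
0.3, 0.05 steps to 0.6, then 0.7 and 0.8). Parameter recovery on off-grid
probe speeds gives a median absolute error well below one grid step.

Decoding matches the *shape* of the response vector: both the measured
vector and the tuning rows are normalised to unit length before the
nearest-row search. Correlator amplitudes scale with the square of the
stimulus contrast, so raw Euclidean matching would couple decoded speed to
contrast and destroy the timing consistency the architecture exists to
deliver; the cross-distance response *ratios* encode speed independently of
amplitude. Raw matching is available via `decode_velocity(normalize =
FALSE)`.

Two floors guard the decode. The absolute floor (1% of the calibration
table's maximum) gates whole frames: below it a frame carries no decodable
motion. Within a gated-in frame, decode validity is *relative* — 1% of that
frame's peak response — because responses scale uniformly with contrast and
an absolute per-pixel floor would clip the low-contrast validity band
asymmetrically, delaying warnings for weak-contrast targets.

## Contour initialisation and the capture range of a balloon-free flow

The printed evolution law has no balloon (expansion) term, so the front
only moves where the edge map varies: the advection basin around a boundary
is ~3–4 px wide, and curvature flow moves a radius-20 front by roughly 3 px
in 300 iterations at `dt = 0.1`. A front seeded more than a few pixels from
the target boundary therefore never arrives. Three consequences shape the
initialisation:

1. The motion-responsive band *trails* the moving boundary in proportion to
   the local boundary speed (about five frames' worth — the effective
   latency of the rectified band-pass response), so a circle fitted through
   the band lies inside the boundary on fast-moving sides.
2. The initial front is accordingly built per direction: a least-squares
   circle fit (refined on the band's angular outer rim) provides the centre;
   along each of 48 rays the front is placed at the deepest edge-map valley
   near the band's outer rim. Directions the band does not cover — the
   optical-stasis side of a diagonal loom, where translation locally cancels
   expansion — are bridged by circular interpolation, which completes the
   gap by construction; the evolution then locks the bridged section onto
   the luminance boundary. With no edge map supplied,
   `initialize_levelset()` falls back to the fitted circle (floored at 5 px
   radius).
3. Each frame is re-initialised from the current motion band rather than
   warm-started from the previous front: once a warm-started front falls
   behind an accelerating boundary it cannot recover (no basin), and mixing
   warm and fresh starts produces flux oscillations. The warm-start path is
   kept behind `contour_params(warm_start = TRUE)`.

The edge indicator normalises each frame's luminance range before the
gradient (the Amacrine stage: average luminance suppressed, boundaries
accentuated). This makes the edge map — hence the extracted contour and the
warning time — independent of object contrast; without it the width of the
saturated valley in `g` scales with edge strength and shifts the arrest
point by a pixel or so across contrasts.

The narrow-band solver sweeps the full band each iteration (band half-width
5 px, redistancing every 25 iterations by polyline redistancing). The
priority-window scheduling of the original front-propagation algorithm is an
efficiency device, not a different flow; the converged contour is the
deliverable, and the plain sweep passes the same convergence fixtures.

## The synthetic stimulus generator

`render_scene()` emulates the evaluation protocol: 30 fps clips of a few
seconds, looming / translating / receding / deforming / multi-object scenes,
rendered with 4× supersampled anti-aliasing, optional seeded Gaussian noise
(default `sigma = 0`), and analytic ground truth (areas from the shape, not
from pixels; annotated collision frame = physical contact, `Z = 0`).
Looming follows a perspective law `rho(t) = rho0 sqrt(tc² + th²) /
sqrt((tc - t)² + th²)` — hyperbolic apparent growth for a constant-speed
approach (`th = 0` is head-on; `th > 0` models an oblique pass). Weber
contrast is `(I_obj - I_bg) / I_bg`, and `contrast_variants()` produces
luminance-only variants sharing bit-identical kinematics.

The deform-loom script morphs a circle to an area-matched square at 55% of
the clip and to a pentagon at 75%, each morph lasting 15% of the clip, with
the base radius frozen during morphs (size increase stalls while boundary
segments move both inward and outward). This reproduces the documented
failure mode: deformation-induced contraction cancels expansion along the
contour and the alarm never fires, even though the object is approaching.

The speed taxonomy (`classify_speed()`: fast if the minimum span for an 8%
relative-area change is ≤ 30 frames, slow if > 50) cannot label any
perspective loom with an in-clip collision "slow": hyperbolic growth makes
the minimum 8%-span about 3.8% of the remaining frames-to-contact, so
`Delta_f > 50` would require a collision more than ~1300 frames away.
The function implements the printed rule and is exercised on constructed
area series; the sweep fixtures are therefore labelled by approach speed
("slower"/"faster" time-to-contact), not by the printed taxonomy.

## Default problem sizes

Package examples, tests and the acceptance script run the pipeline at
160×120 px, 100–120-frame clips (3–4 s at 30 fps, a half-scale version of
the smallest protocol resolution), with the tuning table calibrated once per
session on 12-row drifting-edge strips. These sizes keep a full run at
roughly twenty seconds on one desktop core while leaving every stage's
behaviour — filter warm-up, band tracking, contour convergence, alarm
persistence — identical in kind to full-resolution runs.

## What the synthetic tests do and do not show

The generator produces rigid, uniformly lit objects on clean backgrounds
with exactly shared kinematics across contrast variants. Passing the
contrast-invariance checks shows the architecture is scale-free end to end
(every stage is either linear, relative-thresholded, or shape-matched), not
that real video with texture, glare, shadows and sensor noise would achieve
the same zero fluctuation — on real recordings the reported consistency is
of the order of a couple of frames, not exact. Likewise the selectivity
fixtures show the flux statistic's sign/stationarity logic, not robustness
to background clutter, and the stationary-camera assumption is inherited
from the model: any ego-motion floods the correlator bank with global
responses.

## Known limitations

- Speeds above ~0.8 px/frame decode as zero (outside the delay-line's
  sensitive range); near collision the flux saturates and then collapses,
  so warnings must fire — and empirically do — during the approach phase.
- The balloon-free contour stage depends on initialisation within the edge
  map's capture range; wholly untextured, motion-silent targets larger than
  the band's reach would not be segmented.
- Eq.-style accumulated displacement grids (`accumulate_displacement()`)
  are computed and exposed but unused by the collision stage.
- Video containers are not read directly; decode to PNG/TIFF image
  sequences first.
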