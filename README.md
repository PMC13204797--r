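# loomcontour

Bio-inspired, contrast-independent looming (collision) detection from video.

Collision-warning models inspired by the insect visual system usually trade
one weakness for another: models built on the locust's Lobula Giant Movement
Detector couple warning time to the target's contrast against the background
(a high-contrast object trips the threshold early, a faint one late), while
correlation-based optic-flow models lack spatial selectivity and mix
background dynamics into the collision estimate. `loomcontour` implements a
two-pathway architecture that addresses both: a **motion-sensitive pathway**
decodes a dense velocity field by neuronal population coding, a
**contour-sensitive pathway** extracts the moving target's closed boundary by
geometric curve evolution, and a collision module fuses them through the
**motion flux**

&nbsp;&nbsp;&nbsp;&nbsp;Φ(t) = ∮<sub>C</sub> U·n dl,

the line integral of the decoded velocity's outward-normal component along
the extracted contour C. Looming accumulates positive flux (boundary
velocities align with the outward normals); lateral translation cancels
around a closed curve; recession drives the flux negative. A warning fires
when the flux increments ΔΦ(t) exceed a critical expansion threshold
ξ<sub>th</sub> = 3.5 px²/frame persistently over N<sub>con</sub> + 1 = 5
frames. Because every stage is contrast-scale-free (linear filters, relative
thresholds, shape-matched population decoding, a range-normalised edge map),
the warning time is independent of the target's Weber contrast.

The pipeline, stage by stage:

1. **Retina** — Gaussian ommatidium smoothing (σ₁ = 1 px).
2. **Lamina** — temporal band-pass by a difference of Gamma kernels,
   Γ(2, 3) − Γ(6, 9) (frames).
3. **Medulla** — half-wave rectified ON/OFF channels (Tm3/Tm2) and their
   Γ(25, 30)-delayed counterparts (Mi1/Tm1).
4. **Lobula** — Hassenstein–Reichardt correlators over distances
   β ∈ {2, 4, …, 18} px × 8 directions; per-pixel direction selection,
   population decoding of speed against a calibrated tuning table, dynamic
   motion mask (δ = 0.1 × max response) and dominant region.
5. **Contour** — Gaussian inverse-gradient edge map (σ₂ = 7 on a 0–255
   scale); geodesic-active-contour level set initialised from the dominant
   motion region, evolved by φ_t = gK|∇φ| + ∇g·∇φ (≤ 300 iterations,
   Δt = 0.1) and extracted by marching squares.
6. **Collision** — motion flux, its temporal dynamics, and the windowed
   persistence alarm.

A synthetic stimulus generator (`render_scene()`) provides annotated looming
/ translating / receding / deforming / multi-object scenes with
perspective-projection kinematics, anti-aliased rasterisation, analytic
ground truth and contrast-matched variants, so the whole system is testable
without any recorded video.

## Worked example

```r
library(loomcontour)

# a disc on a 0.5 background approaching head-on at constant speed,
# physical contact at frame 110 of a 120-frame, 30 fps clip
spec <- stimulus_spec("loom", background = 0.5, object_luminance = 0.9,
                      width = 160, height = 120, n_frames = 120,
                      radius0 = 8, collision_frame = 110)
scene <- render_scene(spec)

table <- calibrate_tuning()      # LPTC population tuning, ~10 s, reusable
res <- loom_detect(scene$seq, table, gt = scene$gt)
res
#> <loom_detect> 120 frames (84 with contour); warm-up 63 frames
#>   first collision warning at frame 80
#>   outcome: hit (collision frame 110, lead 30 frames)

plot(res)   # flux trace with warning (blue) and collision (green) markers
```

The flux rises smoothly as the disc expands (about 23 px²/frame at frame 56
to over 100 px²/frame by frame 84); the persistence rule fires at frame 80,
30 frames before contact. Rendering the same kinematics at Weber contrasts
{+0.8, +0.6, +0.4, −0.4, −0.6} and re-running yields the *same* warning
frame for every variant — the contrast-independence the architecture is
designed for:

```r
specs <- contrast_variants(spec, c(0.8, 0.6, 0.4, -0.4, -0.6))
warns <- sapply(specs, function(sp) {
  sc <- render_scene(sp)
  loom_detect(sc$seq, table, gt = sc$gt)$warning_frame
})
warns
#> [1] 80 80 80 80 80
```

A translating disc and a receding disc never alarm (the receding one drives
the flux negative, to about −15 px²/frame), and a looming target that keeps
deforming (circle → square → pentagon) reproduces the documented failure
mode: deformation-induced boundary contraction cancels the expansion cues
and no warning is issued.

## Command line

```sh
inst/cli/loomcontour simulate  --spec stimuli.yaml --out stimdir
inst/cli/loomcontour calibrate --out tuning.json
inst/cli/loomcontour run       --input stimdir/stim_01_loom --table tuning.json --out results
inst/cli/loomcontour sweep     --input dir1,dir2 --table tuning.json --out sweep.csv
inst/cli/loomcontour evaluate  --results results --out summary.json
```

Inputs are PNG/TIFF image-sequence directories (decode video containers to
image sequences first).

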