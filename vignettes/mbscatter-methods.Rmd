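---
title: "Moving-blocker scatter correction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-blocker scatter correction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the acquisition and correction model, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and the places where the design was genuinely open and
a decision had to be made.

## 1. Acquisition model

A cone-beam CT scan is simulated as a point source and flat-panel detector
rotating about the z axis (source-to-axis 1000 mm, source-to-detector
1500 mm by default, matching a common clinical on-board imager). Detector
rows run along the rotation axis; this is also the direction the blocker
moves. The primary fluence at a pixel is `I0 * exp(-p)` with `p` the line
integral of the attenuation volume along the ray to the pixel center,
computed with exact Siddon/Amanatides–Woo voxel intersection lengths. The
same traversal core supplies the ART system-matrix rows, so the simulator
and the reconstructor share one geometry by construction.

The blocker is an array of lateral lead strips specified in
*detector-plane millimetres* (the physical 3.2 mm strips project to the
detector with an unknown source-to-blocker magnification, so the
detector-plane description is the one all processing sees;
`blocker_projected()` converts a physical size given the source-to-blocker
distance). "Pitch" is read as the unblocked gap, so equal width and gap
blocks half the detector — which is also what halves the dose. The strip
pattern is periodic, half-open `[start, start + width)` in mm, and
translated between views by a triangular back-and-forth motion. An
optional finite board extent (`cover`) models a blocker that does not span
the whole detector; this is what creates detector regions without scatter
samples.

Blocked pixels receive only scatter; unblocked pixels receive
primary + scatter; Poisson counting noise is applied to the detected
total at `I0 = 1e5` counts/pixel by default, with a mandatory seed.

## 2. The scatter generator

Real scatter is not modelled physically here (no Monte-Carlo transport,
no polychromatic beam). What the correction method *assumes* is only that
scatter is a smooth, low-frequency additive field, so the generator
produces exactly that, in a form with a closed-form oracle: the per-view
scatter is a Gaussian low-pass (σ = 40 mm at the detector by default) of
the fluence deficit `I0 - primary`, rescaled so that the mean
scatter-to-primary ratio over the object shadow equals a prescribed SPR
(default 1.0, a realistic magnitude for unblocked flat-panel CBCT of a
body-sized object). Because the primary rotates slowly with the gantry,
the generated scatter also changes slowly from view to view — the property
the multi-view method relies on.

What this does *not* emulate: object-dependent scatter kernels, detector
glare and lag, beam hardening, the blocker's own scatter, or
primary transmission through the strip penumbra. Consequently, passing
tests show that the estimation and reconstruction machinery is correct
under the stated smoothness assumption; they do not certify performance
on any particular scanner. The penumbra is handled operationally instead:
scatter samples are drawn from an *eroded* mask that trims 2 pixels from
each side of every blocked band.

## 3. Blocker-edge detection

Two detectors are implemented.

**Two-point method.** At two probe columns, blocked bands are runs of the
axial profile below a fixed fluence threshold; each band edge is the
straight line through its two detected rows. This is the classical
approach and the package reproduces its known failure: a perturbation of
one probe point by Δ rows tilts the line by Δ divided by the probe
separation, so the edge error at a column at distance d is `Δ·d/sep` —
small probe separations amplify small errors into many-pixel mistakes.

**Minimum envelope + adaptive threshold.** The pointwise minimum of the
axial profiles of a few adjacent views approximates the scatter profile
directly, because every axial position is blocked in at least one nearby
view once the band offsets of the window tile the strip period. From the
envelope, a per-row threshold

```
t(z) = S(z) + alpha * (U(z) - S(z))
```

separates blocked from unblocked rows, where `S` is the smoothed envelope
(scatter proxy; running mean over half a strip period) and `U` is the
local total level. Neither `S + alpha(U-S)` nor the construction of `U`
is prescribed anywhere as a formula, so both are declared design
decisions of this package:

* `U` is a grayscale *closing* (running maximum then running minimum,
  window = one strip period). A bare running maximum smears bright
  regions across sharp object-shadow steps and produces false blocked
  rows just inside the shadow; closing fills the blocked valleys to the
  surrounding plateau without displacing step edges.
* `S` is clamped at `U`: the running-mean smoothing of the envelope can
  overshoot above the local total near sharp steps, which would make the
  threshold meaningless there.
* `alpha` defaults to 0.5 (mid-gap). Any value in (0, 1) works on clean
  profiles; small values shrink the detected bands toward rows exactly at
  scatter level.
* Runs narrower than half a strip width are discarded as threshold
  chatter, except at the detector border where genuinely clipped bands
  occur.
* Band boundaries are refined per column within ±3 rows of the run
  boundary, then a least-squares line is fitted per edge, keeping the
  straight-edge model of the two-point method.

Degenerate inputs (no blocker contrast, `U ≈ S` everywhere) raise an
error rather than returning empty band sets.

## 4. Scatter estimation

The scatter profile of view *i* at one lateral column is
`S_i(z) = Σ_k a_k W_k(z)` with cubic B-splines `W_k` on uniform knots
spanning the sampled axial range. The weights minimize the summed squared
misfit over all blocked-region samples of the neighbourhood `N(i)`
(single-view: `N(i) = {i}`). The number of basis functions defaults to
one per strip period across the sampled range plus 4 — enough to follow
a smooth profile sampled once per period without chasing noise.

Numerical choices:

* The objective is linear in the weights, so the normal equations are
  solved directly by Cholesky; this is the one-step limit of any
  iterative scheme for this problem. A ridge of 1e-8 is added only if the
  factorization fails (near-singular design); well-posed fits are
  therefore the exact least-squares solution, which is what the QR-oracle
  tests compare against at 1e-8 relative.
* Basis functions whose support contains no sample raise an error naming
  the uncovered knot span rather than producing a silently wild fit.
* Beyond the outermost sample the evaluated profile is clamped to its end
  value. Constant extrapolation is deliberately conservative: the
  single-view boundary failure this package studies *is* the error of
  extrapolating a varying profile, and any richer extrapolant would just
  relocate that error. The multi-view fit makes extrapolation largely
  unnecessary instead.
* Lateral dimension: the spline model is axial; independent per-column
  fits are followed by an 11-column lateral moving average. Columns whose
  member views share identical sample rows (the common case, since strips
  block whole rows) share one factorization and are solved multi-RHS.
* The neighbourhood is a contiguous window of `n_adjacent` views
  (default 5) containing the target, shifted inward at the scan ends. A
  hard angular span cap rejects windows over which scatter could change
  materially; the default cap is 3°, the regime in which more views stop
  helping on densely sampled clinical scans. The bundled desk-scale
  fixtures use 60 views over 360° (6°/view), where the generator's
  scatter is rotationally almost invariant by construction, and therefore
  set the cap to 30°; this is a property of the synthetic scatter, not a
  recommendation for real data.

Correction then forms `p = -ln(max(total - scatter, floor)/I0)` on
unblocked pixels with `floor = 1e-6 I0`, counts clamped pixels, and warns
if more than half a view's unblocked pixels clamp (a sign of a badly
wrong scatter estimate). Blocked pixels are masked `NA` and never enter
reconstruction.

## 5. Reconstruction

TV-constrained ART in the adaptive-steepest-descent style: each pass
sweeps the usable rays in sequential Kaczmarz updates (relaxation
λ = 0.5), clamps at zero, then takes `tv_steps = 10` normalized
steepest-descent steps on the total variation with step size
`0.2 ×` the norm of the pass's ART update, backtracking (halving, up to
10 times) whenever a step would increase the TV, so the TV is
non-increasing across a descent call by construction; positivity is
re-imposed after the descent. Views are visited in bit-reversed order so
each pass spreads its angular coverage; rays run column-major within a
view. Rays that miss the grid are skipped and counted.

The data-fidelity stop `ε` is not prescribed numerically anywhere, so the
default stop is a residual plateau (relative change < 1e-4) with an
optional explicit `ε`; a residual rising for three consecutive passes
aborts with the trace. The TV value uses a smoothing constant
δ = 1e-8 inside the root, so a constant volume evaluates to
`sqrt(δ) ×` the number of interior terms rather than exactly zero — the
tests bound it accordingly.

Test problem sizes (64³ volumes at 2 mm, 96² detectors at 2 mm, 60
views, ≤ 30 passes) were chosen as the smallest grids on which the
boundary and robustness scenarios are geometrically expressible with
several strip periods across the object shadow; the same sizes are used
by the acceptance script.

## 6. The bundled fixtures

`make_fixture()` returns three complete study configurations sharing one
geometry (water-equivalent cylinders, equal projected strip width and gap
of 16 mm, SPR 1, Poisson noise at `I0 = 1e5`):

* **clean** — water cylinder with a central air insert, full blocker
  coverage. Both estimators' assumptions hold; CT numbers should be
  accurate (air near −1000 HU) and the two estimators should agree.
* **boundary** — the blocker board ends 70 mm up the detector axis while
  the object shadow (and hence the scatter transition) continues to the
  detector edge. Single-view estimation must clamp-extrapolate across the
  falling scatter profile; the five-view window reaches up to ~26 mm
  further and supplies real samples there. The board extent was chosen so
  that the un-sampled end region is of the same order as the multi-view
  reach — the configuration in which adjacent views *can* repair the end
  region; a much larger deficit is unrepairable by any projection-domain
  method and a much smaller one shows no failure to repair.
* **robustness** — a wide low-contrast cylinder, two-point probe columns
  only 8 columns apart (as forced on low-contrast scans where few
  columns give reliable crossings), and a simulated +3-row mis-detection
  at the second probe in every tenth view, which the straight-line edge
  model amplifies to tens of pixels at distant columns. The
  envelope-based path never uses the probes and is unaffected.

The fixtures' blocker motion (triangular, amplitude 64 mm = two strip
periods, period 10 views) moves the band pattern by ~40% of a strip
period per view, so a five-view window multiplies the axial sampling rate
several-fold and its band positions tile the period — the regime the
multi-view method is designed for. The slow default motion of
`blocker_trajectory()` (amplitude one period over 40 views) is closer to
a cautious hardware setting but gives a five-view window little new
coverage at desk scale, which is why the fixtures override it.

## 7. Projector validation

Siddon traversal is exact for the voxelized volume, and two independent
oracles check it: a segment-walk/slab-clipping oracle for the traversal
geometry on arbitrary rays, and analytic cylinder chords for the physics.
The chord comparison is run over rays transversal to the cylinder wall
(a narrow fan, impact parameter ≲ 0.35 r). At shallow incidence the
difference between a rasterized and a continuous cylinder — of order
`mu · voxel/2 · tan(incidence)` per wall crossing, irrespective of how
finely the boundary voxels are anti-aliased — dominates any projector
error, so grazing rays test the phantom representation, not the
projector; the transversal restriction keeps the oracle probing the
latter.

## 8. Conventions and limitations

* R-native 1-based indexing throughout; all physical quantities in mm and
  fluence counts; angles in degrees ascending over [0, 360), view 1
  at 0°.
* Full-fan geometry only; half-fan (laterally offset detector) scans are
  out of scope, as are curved blocker-edge models, deconvolution of
  primary contamination in blocked regions, analytic (FDK)
  reconstruction, and Monte-Carlo scatter.
* The evaluation benchmark is the ground-truth phantom volume standing in
  for a reference modality; registration to real reference scans is out
  of scope.
* Determinism: every random stage derives its sub-seed from the single
  run seed, so identical configurations produce identical artifacts.
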