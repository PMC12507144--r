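---
title: "Methods: aortic 4D flow hemodynamics in aortaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aortic 4D flow hemodynamics in aortaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices and limitations. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## Data model

A 4D flow dataset is three velocity component volumes plus a signal
magnitude volume on one `[nx, ny, nz, nt]` grid (`VelocityField`), and
a binary lumen mask (`Segmentation`). Velocities are held in m/s,
voxel spacing in mm, temporal resolution in ms; spacing is converted
to meters exactly where spatial derivatives or world coordinates are
formed, never earlier, so Pa and m/s outputs cannot silently pick up
factors of 10^3. The grid is axis-aligned with world coordinates
`(index - 1) * spacing`; orientation matrices of real scanner data are
out of scope because every validation dataset is generated on this
grid. Background phase-offset correction is likewise not implemented —
scanners apply it during reconstruction — but the phantom generator
can add a constant offset (`phaseOffset`) so downstream robustness can
be probed.

The PC-MRA used for segmentation is the time average of
`magnitude x |v|`; peak systole is the timeframe maximizing the
spatially averaged lumen speed (earliest frame on ties). Frames are
1-based throughout, the R convention.

## Wall geometry

The wall is sampled at one point per exposed voxel face of the
segmentation. Inward normals are the normalized negative gradient of
the signed Euclidean distance transform of the mask (computed exactly
by a separable lower-envelope algorithm in C++, with anisotropic
spacing support), after a light `[1 2 1]/4` separable smoothing of the
signed distance; without that smoothing, gradient directions inherit
the staircase of the binary surface (on a digital sphere the mean
angular error roughly halves with it). Local lumen diameter is
measured by marching along the inward normal at a quarter of the
smallest voxel spacing until the ray re-crosses the wall; rays leaving
the grid mark the point invalid (`NA`), never zero.

The centerline is the ridge of the interior distance transform: lumen
voxels form a 26-connected graph with edge weights `length / inradius`,
the two vessel ends are the mutually farthest voxels (double geodesic
sweep) snapped to the most interior voxel of each end region, and the
minimal-cost path between them is smoothed (3-sample moving average on
the voxel path, then a 5-sample pass on the 2 mm resampled polyline)
and refined to sub-voxel accuracy by moving every sample to the
inradius^2-weighted centroid of its orthogonal lumen slab. The
refinement matters: a voxel-quantized path sits up to half a voxel off
the true axis, consistently to one side, which both biases flow
sections and flips inner/outer labels near the split plane. On the
straight validation phantom the refined centerline deviates from the
analytic axis by under 0.15 mm at 2.5 mm voxels. Because the ends of a
capped or field-of-view-clipped vessel cannot carry a meaningful
centerline, the traced centerline starts about one radius inside each
end; landmark positions given in analytic arc length are therefore
mapped onto the measured centerline through their spatial positions
(`phantomGeometry()` does this for phantoms).

Masks that are not simple tubes are rejected by a coverage check:
every lumen voxel must lie within ~1.5 tube radii of the traced path,
which catches side branches and slab-like masks.

## Six-region partition

The longitudinal class (ascending aorta, arch, descending aorta) of a
wall point or lumen voxel follows the arc length of its nearest
centerline sample against the three configured landmarks
(brachiocephalic trunk, left subclavian artery, diaphragm); landmarks
are configuration inputs, as they are located manually in practice.
Points beyond the last landmark are labelled `none`.

The inner/outer side is this package's operational definition of a
convention that is usually applied visually: where the centerline is
strongly curved (curvature at least 1/m *and* at least 40% of the arch
apex curvature, measured over a ~10 mm stencil so voxel-scale tangent
noise does not masquerade as anatomy), the side follows the sign of
`(p - c) . k_hat`, `k_hat` the local curvature normal pointing toward
the center of curvature ("inner" faces the arch center). Elsewhere the
split direction is the vector from the sample toward the center of
curvature at the arch apex, projected orthogonal to the local tangent.
A literal fixed plane through the apex was rejected: with the apex
curvature normal as its normal, both straight limbs of a U-shaped
vessel fall on the same side of that plane, contradicting the
anatomical meaning of inner/outer. For entirely straight vessels there
is no curvature to appeal to and an explicit `splitDir` must be
supplied. On U-bend phantoms with known sides, at least 95% of
ground-truth inner points are labelled `inner_*` (the residual sits
within a voxel of the split plane).

Lumen voxels are assigned to regions by the same rule applied to voxel
centers (the nearest wall point would give the identical longitudinal
class in a tube; the centerline rule is cheaper and stabler).

## Wall shear stress

WSS follows the near-wall velocity-gradient method: with local
diameter D, velocity is sampled by trilinear interpolation at D/4 and
D/2 along the inward normal — together with the no-slip zero at the
wall, three points spanning half the lumen diameter. Samples are
projected onto the wall-tangent plane, and per tangential component
the unique quadratic through the three points gives
`WSS = mu * dv/ds` at the wall, i.e. `(4 v1 - v2) / (2 s1)` with
`s1 = D/4`. The quadratic is exact for linear and parabolic profiles,
so on the analytic Poiseuille cylinder the only error sources are
interpolation and wall placement. The viscosity default is
mu = 3.2e-3 Pa s, the conventional blood value in this method lineage
(the underlying studies do not state one); it is a plain argument.

Two guards keep degenerate points out: samples falling outside the
grid mark a point missing, and points whose diameter exceeds
`maxDiameterFactor` (default 3) times the median valid diameter are
treated as invalid — these are points whose "diameter" ray ran along
the lumen rather than across it, e.g. on the capped ends of a phantom
or a field-of-view-clipped aorta. Missing is always `NA`, never 0, so
region means cannot be silently dragged down.

Accuracy on the noise-free Poiseuille cylinder (R = 10 mm,
vmax = 1 m/s, analytic WSS 0.64 Pa): the mean estimated magnitude is
within 8% at 2.5 mm voxels and within 4% at 1.0 mm, and the mean
absolute per-point error decreases monotonically with resolution
(about 13% / 8% / 6% at 2.5 / 1.5 / 1.0 mm). The residual negative
bias is the classic staircase effect: face-centroid wall anchors on a
convex wall sit slightly outside the true surface on average.

## Normative atlas and abnormality maps

The atlas stores, per lumen voxel (velocity) and per wall point (WSS)
of a shared geometry, the cohort mean vector, mean magnitude and
sample SD of the magnitude (n - 1 denominator). A location is defined
only where at least 80% of subjects (and no fewer than 2) contribute.
The normative band is `mean ± 1.96 SD`; *elevated* means strictly
above the upper bound (one-sided — decreased values are deliberately
not flagged, matching how elevated-flow maps are read), and
*abnormally directed* means a vector angle above 120° versus the atlas
mean vector. Direction is not evaluated where either vector magnitude
is below 0.01 m/s (velocity) or 0.01 Pa (WSS): the angle between
near-zero vectors is numerically meaningless. A patient is abnormal in
a region when at least one of its locations is flagged; incidence maps
divide per-location flag counts by the number of covering patients.

Patients on a different grid are mapped through a rigid transform and
nearest-neighbor lookup. The rigid registration itself optimizes mask
overlap (soft Dice against the trilinearly interpolated fixed mask)
with centroid initialization and Nelder-Mead refinement over three
rotations and three translations — segmentations are registered, not
images, matching how follow-up geometry is aligned to baseline.
Deformable co-registration is out of scope; with phantom cohorts on a
shared template grid, voxelwise statistics need no registration at
all, which isolates hemodynamic variability from registration error.

Calibration on the null: a held-out healthy subject drawn from the
same generative distribution as a 25-subject atlas has an
elevated-voxel fraction of a few percent (the one-sided 97.5% bound
would give 2.5% exactly if the atlas moments were known rather than
estimated at n = 25).

## Pulse wave velocity

The field is first resampled in time by periodic Fourier
interpolation onto `round(cycle / 20 ms)` uniform frames — exact for
band-limited periodic signals, mean-preserving to machine precision,
and harmonic-preserving for the wavelet stage. The effective frame
spacing is `cycle / n_new`, equal to the 20 ms target whenever the
target divides the cycle (the phantom defaults, 30 frames at 32 ms,
make it exact).

Flow waveforms are integrated on cross-sections every 10 mm along the
centerline: lumen voxels within half a voxel of the orthogonal plane
(along the tangent) and within 2.5 local inradii of the axis (so a
neighboring limb of a curved vessel cannot leak into the plane)
contribute `(v . t_hat) * voxelVolume / slabThickness`. Sections with
fewer than 4 voxels, or within 5 mm of the vessel ends, are dropped.
Sections are oriented along the mean flow direction, so "proximal" is
upstream regardless of how the centerline was traced.

Each section's delay against the most proximal section (a fixed,
reproducible reference choice) is computed from the complex Morlet
continuous wavelet transform (center frequency omega0 = 6, circular
convolution — the cycle is periodic) over 24 log-spaced scales whose
Fourier periods span `2 dt` to half the cycle: the cross-spectrum
`C = W_ref conj(W_i)` is reduced to the cross-power-weighted average
of `phase(C) / omega` over the points with `|C|` at least 50% of its
maximum, and the total `|C|` over that region becomes the section's
weight. The 50% mask and omega0 are exposed as arguments; the weighted
phase delay was chosen over a cross-correlation peak because it is
sub-sample accurate and robust to modest waveform shape change. PWV is
the inverse slope of the weight-weighted least-squares regression of
delay on arc length; results with non-positive slope or R^2 < 0.5 are
marked invalid.

On straight phantoms 0.3 m long with 30 frames at 32 ms, true PWV of
5, 8 and 12 m/s is recovered within 5% noise-free and within 10% at
SNR 20 (10 seeded replicates each). The estimator carries a small
positive bias (~4%) from the finite scale band; it is stable across
seeds.

## Synthetic phantoms

`makePhantom()` builds straight or U-bend tubes with pulsatile laminar
flow: axial velocity `vmax w(t - s/PWV) (1 - r^2/R^2)`, with `w` the
periodic cycle waveform linearly interpolated between its samples and
`s` the centerline arc length — so the waveform propagates at exactly
the prescribed PWV with zero dispersion, isolating estimator error.
Poiseuille rather than Womersley profiles keep WSS (`2 mu vmax / R`)
and flow (`pi R^2 vmax / 2`) in closed form. Gaussian noise of the
stated SD is added to every velocity component inside and outside the
lumen; the magnitude image is 1 (magnitude weighting is not exercised
by any downstream result). Defaults mirror a thoracic-aorta
acquisition: 2.5 mm isotropic voxels, 30 frames at 32 ms (a 960 ms
cycle), peak velocity 1 m/s, PWV 8 m/s, noise 0.05 m/s (SNR 20
relative to the peak velocity). The default waveform is a smooth
systolic Gaussian pulse (peak at 25% of the cycle, width 8%) on a 5%
diastolic baseline — physiologically shaped and band-limited enough
for exact Fourier resampling.

Two deliberate generator design rules:

- tubes are **capped inside the grid** (a mask touching the grid
  boundary is an error, since wall normals are undefined there), so
  phantom end caps stand in for the field-of-view clipping of real
  scans; the diameter guard above keeps them out of WSS summaries,
  and landmark defaults keep them out of the named regions where
  possible;
- tubes are placed **off the voxel lattice** (fixed sub-voxel offsets
  of spacing/pi, spacing/e, spacing/sqrt(5)): a grid-commensurate
  cylinder — axis on a voxel center, radius an integer multiple of
  the spacing — puts entire rings of voxel centers exactly on the
  wall, a degenerate alignment real anatomy never exhibits, and one
  that produces pathological wall-anchor biases at exactly the
  commensurate spacings.

Cohorts (`makeCohort()`) perturb peak velocity and optionally radius
by log-normal multipliers `exp(N(0, sd^2))` on a shared template grid;
with `radiusSD = 0` (the default) the geometry is shared exactly and
atlas statistics are free of registration error. All randomness flows
from the spec seeds; identical specs give bit-identical datasets.

What the phantoms do **not** emulate: secondary/helical flow in
bends, turbulence, non-Newtonian rheology, valve jets, wall motion and
compliance, velocity aliasing, eddy-current offsets beyond a constant,
and realistic anatomical variability beyond scale factors. Passing
tests therefore demonstrate correctness of the estimators under their
stated assumptions and their noise robustness — not clinical accuracy
on patient data.

## Numerical choices and degenerate inputs

- Exact Euclidean distance transforms (no chamfer approximation);
  infinities replaced by a large finite sentinel in the
  lower-envelope recursion, which is otherwise undefined for
  empty-feature lines.
- Trilinear interpolation everywhere a field is sampled off-grid;
  outside-grid samples are `NA` and propagate to "missing", never 0.
- Ties: peak systole takes the earliest frame; nearest-centerline and
  nearest-wall lookups take the first minimum.
- Zero-variance inputs: paired t on zero-variance differences reports
  *undefined* rather than a fabricated p; Fisher on an all-zero table,
  Pearson on constant vectors, and ICC with zero between-subject
  variance are errors.
- McNemar without discordant pairs returns `NA`, the convention used
  in incidence tables.
- Exact McNemar is the two-sided binomial test on `min(b, c)` with
  n = b + c, p0 = 0.5; two-sided Fisher sums hypergeometric
  probabilities not exceeding the observed table's (the most common
  convention; both verified against brute-force enumeration).
- The independent-samples t is the classical pooled-variance Student
  test (the studies this mirrors report "Student's"), not Welch.
- Report percentages round half away from zero (base R's `round()` is
  round-half-even and would print 46% as 46 but 0.5-boundary cells
  differently than the published tables).
- No multiple-testing correction anywhere, matching the statistical
  battery this package mirrors.

## Validation problem sizes

The shipped tests and the acceptance script use: Poiseuille cylinders
R = 10 mm x 80 mm at 2.5 / 1.5 / 1.0 mm voxels (WSS); straight tubes
0.3 m long, 30 frames at 32 ms (PWV, 3 noise-free runs plus 10 noisy
replicates per speed); U-bend templates R = 8 mm with 25-subject
cohorts (atlas, regions); a demo pipeline of 25 healthy subjects plus
6 patients at two sessions; 1000-2000 replicates for the statistical
coverage, power and type-I checks; and full enumeration of 2x2 tables
with total up to 40 for the exact-test oracles. These sizes were
chosen so the entire validation runs comfortably on a laptop-class
single core while keeping Monte-Carlo error well below the asserted
tolerances.

## Known limitations

- Rigid registration only; deformable atlas mapping is not provided.
- The inner/outer rule assumes a single dominant bend (a C-shaped
  vessel); S-shaped geometries would need per-segment split
  directions.
- The centerline does not extend into capped or clipped vessel ends
  (about one radius is lost per end).
- WSS at 2.5 mm voxels carries the known staircase underestimation of
  this estimator class; comparisons should stay within one protocol.
- The PWV delay estimator assumes a periodic cycle and a single
  propagating waveform; severe regurgitant or bidirectional flow
  violates that.
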