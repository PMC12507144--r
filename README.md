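# aortaflow

Quantitative analysis of time-resolved three-directional phase-contrast
MRI ("4D flow MRI") of the thoracic aorta, in R.

4D flow MRI measures the blood-velocity vector field **v**(x, t) over a
3D volume through the cardiac cycle. From such a dataset — the three
velocity component volumes, the signal magnitude, and a binary lumen
segmentation — the package computes the hemodynamic markers used in
longitudinal aortic studies (e.g. of Marfan-syndrome cohorts):

- **Wall shear stress (WSS)** at peak systole: at every wall point the
  velocity is sampled at D/4 and D/2 along the inward normal (D the
  local lumen diameter), the no-slip condition anchors the profile at
  the wall, and WSS = μ·∂v_t/∂n from the unique quadratic through the
  three points (μ = 3.2 mPa·s by default). Peak systole is the
  timeframe with the highest spatially averaged lumen speed.
- **Six-region summaries**: mean velocity and WSS in the inner and
  outer ascending aorta, arch, and descending aorta, bounded by the
  brachiocephalic, left-subclavian and diaphragm landmarks along an
  automatically extracted centerline.
- **Normative atlases and abnormality maps**: a healthy-cohort atlas
  stores the voxelwise mean and SD of velocity and WSS on a shared
  geometry; a patient location is *elevated* when its magnitude exceeds
  mean + 1.96·SD, and *abnormally directed* when its vector deviates by
  more than 120° from the atlas mean vector. Per-region flags (any
  abnormal location) and cohort incidence maps (% of patients abnormal
  per location) follow.
- **Pulse wave velocity (PWV)**: flow waveforms Q(t) are integrated on
  cross-sections every 10 mm along the centerline (after Fourier
  resampling to 20 ms temporal resolution), each section's delay
  relative to the most proximal section is the cross-power-weighted
  phase delay of the Morlet wavelet cross-spectrum, and PWV = 1/slope
  of the weighted delay–distance regression.
- **Cohort statistics**: paired/unpaired Student t with 95% CI, exact
  Fisher and McNemar tests, Pearson correlation, ICC(2,1) absolute
  agreement, and table-style CSV reports.

Because clinical 4D flow data cannot be redistributed, the package
ships a **synthetic phantom generator**: straight or U-bend tubes with
pulsatile Poiseuille flow whose waveform propagates along the
centerline at an exactly known PWV, with Gaussian velocity noise and
log-normal between-subject variability for atlas cohorts. Every stage
is validated against the phantoms' analytic ground truth.

## Worked example

A pulsatile U-bend phantom at study-like resolution (2.5 mm, 20 frames
at 40 ms, peak velocity 1 m/s, PWV 8 m/s, SNR 20):

```r
library(aortaflow)

spec <- phantomSpec("u-bend", radius = 8, length = 30, bendRadius = 22,
                    vmaxPeak = 1, noiseSD = 0.05, seed = 7,
                    waveform = defaultWaveform(20), dt = 40)
ph  <- makePhantom(spec)
geo <- phantomGeometry(ph)           # wall mesh, centerline, regions
pf  <- peakSystoleIndex(ph$field, ph$seg)
wss <- estimateWSS(ph$field, geo$mesh, pf)
wss
#> WSSField at frame 6 (mu = 3.20e-03 Pa s): 1425/1442 valid points
#>   mean |WSS| 0.723 Pa

regionMeans(ph$field, wss, geo$mesh, ph$seg, geo$centerline, pf)
#>       region velocity_mps wss_pa n_voxels n_wall_points
#> 1  inner_AAo        0.520  0.722      192           158
#> 2  outer_AAo        0.507  0.719      192           155
#> 3 inner_arch        0.526  0.768      358           289
#> 4 outer_arch        0.481  0.734      498           474
#> 5  inner_DAo        0.510  0.663      224           187
#> 6  outer_DAo        0.445  0.688      181           162

estimatePWV(ph$field, ph$seg, centerline = geo$centerline)
#> PwvFit: PWV 9.23 m/s, R^2 0.836, 11 sections
```

The mean WSS of ~0.7 Pa at 1 m/s peak velocity and the PWV estimate
within ~15% of the 8 m/s ground truth on this deliberately short
(~13 cm) vessel are typical of the resolution; on the longer straight
phantoms used for validation the PWV error is below 5% without noise
and below 10% at SNR 20.

The full pipeline — healthy atlas cohort, patients at two sessions,
abnormality maps, incidence maps, PWV, and `table1.csv` … `table4.csv`
reports — runs from a YAML config:

```r
runPipeline(system.file("extdata", "demo-config.yaml",
                        package = "aortaflow"), "out/")
```

or from a shell via `inst/scripts/aortaflow run-all --config cfg.yaml
--out out/`. Reruns with the same config are bit-identical.

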