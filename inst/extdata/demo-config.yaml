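# Demo pipeline configuration: a 25-subject healthy atlas cohort and 6
# patients with elevated peak velocity, imaged at two sessions on a
# U-bend phantom at study-like resolution (2.5 mm, 32 ms).
seed: 42
template:
  geometry: u-bend
  radius: 8          # mm
  length: 25         # mm per straight arm
  bend_radius: 20    # mm
  spacing: 2.5       # mm, isotropic
  dt: 32             # ms
  nt: 20             # timeframes per cycle
  vmax_peak: 1.0     # m/s
  pwv_true: 8        # m/s
  noise_sd: 0.05     # m/s (SNR 20 vs vmax)
cohort:
  n_healthy: 25
  n_patients: 6
  vmax_sd: 0.1             # log-SD of between-subject peak velocity
  patient_vmax_factor: 1.4 # patients run hotter than the atlas cohort
mu: 0.0032           # Pa s
atlas:
  ci_factor: 1.96
  angle_deg: 120
pwv:
  dt_target: 20      # ms
  section_spacing: 0.010  # m
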