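# Example study configuration: per-condition SD scenarios (condition medians)
# and the perivascular-map settings. All values are inputs, not constants of
# the package.
n_slices: 12
seed: 1

scenarios:
  control:                  # aCSF
    baseline_cmro2: 34.4    # mmHg/s
    peak_ratio: 2.7
    dc_duration: 43         # s
    delta_k: 22.6           # mM
    t1_50: 20.0             # s
    t2_50: 65.0             # s
  iso1:                     # 1 vol% isoflurane (light anesthesia)
    baseline_cmro2: 34.4    # baseline not significantly changed
    peak_ratio: 2.145       # 1 + delta-CMRO2 39.4 over baseline
    dc_duration: 60
    delta_k: 22.6           # peak transient not significantly changed
    t1_50: 20.0
    t2_50: 65.0
  iso3:                     # 3 vol% isoflurane (deep anesthesia)
    baseline_cmro2: 30.7    # reduced pre-SD consumption
    peak_ratio: 1.60        # 1 + delta-CMRO2 18.4 over baseline
    dc_duration: 107
    delta_k: 16.5
    t1_50: 38.3
    t2_50: 235.7

# CMRO2 levels (mmHg/s) for the perivascular oxygenation maps
map_cmro2:
  baseline: 34.4
  sd: 92.0
  iso3_baseline: 30.7
  iso3_sd: 49.1

slice:
  surface_po2: 400          # mmHg, interface-chamber supply at the surface
  domain_depth: 160         # um, deepest electrode = ptiO2 minimum
  km: 3                     # mmHg
  diffusion_constant: 1600  # um^2/s

krogh:
  capillary_po2_grid: {from: 20, to: 55, by: 1}   # mmHg
  radius_grid: {from: 10, to: 35, by: 1}          # um
  capillary_radius: 2.5     # um; tuned within the plausible 2-4 um range
  threshold: 8              # mmHg hypoxia threshold
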