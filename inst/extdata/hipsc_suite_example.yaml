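# Example configuration for run_scenario_suite(): a reduced hiPSC-CM
# remodeling suite. Units are normalized internally to ms / cm / mV.
experiment: hipsc_suite
mesh:
  nx: 40
  ny: 40
  dx_um: 250
duration_s: 20
intensities: [0.5]
patch_radius_cm: 0.5
target_fraction: 0.5
seeds: [101, 202, 303]
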