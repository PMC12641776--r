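# Example analysis configuration: keys override default_config().
# Protocol constants (grid, filters, exclusion bands) are shown at their
# standard values; detector thresholds may be re-tuned per dataset.
min_cells_per_square: 200
mask_exclusion_fraction: 0.90
pr_exclusion_deg: 2.5
n_bins: 25
ecc_range_deg: [-10.0, 10.0]
detector:
  response_threshold_frac: 0.3
vessel:
  dark_fraction: 0.75
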