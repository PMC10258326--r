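# Example configuration (synthetic-trial mode). Keys omitted here inherit
# the package defaults; monetary values flagged as placeholders in the
# defaults remain placeholders until replaced with local unit costs.
wtp: 37654
settings:
  horizon_years: 10
  discount_rate_costs: 0.05
  discount_rate_effects: 0.05
trial:
  n_total: 465
  pfs_median_tc: 8.3
  pfs_median_pc: 5.6
  os_median_pc: 17.1
  followup_median: 16.2
schedule:
  induction_cycles: 6
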