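# Desk-scale study configuration: 5 districts, 2,000 mothers, 200 replicates.
# Full-scale counts (25 districts, 46,007 mothers, 1,000 replicates) are set
# by region: {scale-like overrides below}; expect hours of runtime at that
# size.
region:
  n_districts: 5
  n_neighbourhoods: 20
  n_tracts: 800
  n_roadside_monitors: 3
  n_grid_points: 100
  n_mothers: 2000
  region_extent: 25000
  covariate_count: 5
  seed: 42
scenarios: [ES2, ES8]
methods: [TE, NM, IDWA, LUR, UK, AA, UKD, UKNA, UKCA, UKGA]
n_replicates: 200
master_seed: 1
health:
  true_rr: 1.0033
  baseline_prevalence: 0.05
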