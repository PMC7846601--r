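# Synthetic site preset "cas0": thin-end of the paludification gradient.
# 38 cm organic layer, basal age ~1255 cal yr BP, last fire ~175 cal yr BP
# capping a fast Sphagnum acrotelm over dense woody peat.
site_id: cas0
coring_year: 2017
om_fraction: 0.95
segments:
  - {thickness: 10, dep_time: 3.0, om_density: 0.075}
  - {thickness: 10, dep_time: 3.4, om_density: 0.085}
  - {thickness: 4, dep_time: 44.5, om_density: 0.11}
  - {thickness: 14, dep_time: 77.142857, om_density: 0.178}
fires:
  - {top: 24, bottom: 26, count: 30}
  - {top: 30, bottom: 31, count: 18}
c14_depths: [24, 31, 38]
c14_sigmas: [45, 50, 57]
pb210_depth: 30
pb210_flux: 160
supported: 15
pb210_cv: 0.05
cohort:
  n_trees: 20
  establishment_year: 1839
  last_year: 2018
  dbh_target: 10.0
  dbh_sd_frac: 0.20
  growth_k: 0.05
  growth_t0: 60
  width_cv: 0.10
  plot_area: 100
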