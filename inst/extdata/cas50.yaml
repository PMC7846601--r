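# Synthetic site preset "cas50": mid-transect, 69 cm organic layer,
# basal age ~7667 cal yr BP, last fire ~177 cal yr BP.
site_id: cas50
coring_year: 2017
om_fraction: 0.95
segments:
  - {thickness: 10, dep_time: 3.3, om_density: 0.08}
  - {thickness: 10, dep_time: 3.8, om_density: 0.09}
  - {thickness: 5, dep_time: 34.6, om_density: 0.11}
  - {thickness: 44, dep_time: 170.227273, om_density: 0.158}
fires:
  - {top: 25, bottom: 27, count: 28}
  - {top: 40, bottom: 41, count: 22}
  - {top: 55, bottom: 56, count: 35}
c14_depths: [25, 40, 55, 69]
c14_sigmas: [45, 50, 60, 57]
pb210_depth: 30
pb210_flux: 160
supported: 15
pb210_cv: 0.05
cohort:
  n_trees: 20
  establishment_year: 1839
  last_year: 2018
  dbh_target: 9.1
  dbh_sd_frac: 0.20
  growth_k: 0.04
  growth_t0: 65
  width_cv: 0.10
  plot_area: 100
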