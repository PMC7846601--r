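# Synthetic site preset "cas100": most paludified site, 95 cm organic
# layer, basal age ~7522 cal yr BP, last fire ~176 cal yr BP; ligneous
# low-CAR horizon between 26 and 50 cm.
site_id: cas100
coring_year: 2017
om_fraction: 0.95
segments:
  - {thickness: 10, dep_time: 3.2, om_density: 0.078}
  - {thickness: 10, dep_time: 3.7, om_density: 0.088}
  - {thickness: 6, dep_time: 29.0, om_density: 0.105}
  - {thickness: 24, dep_time: 170.0, om_density: 0.16}
  - {thickness: 45, dep_time: 72.577778, om_density: 0.157}
fires:
  - {top: 26, bottom: 28, count: 26}
  - {top: 45, bottom: 46, count: 20}
  - {top: 70, bottom: 71, count: 30}
c14_depths: [26, 45, 70, 95]
c14_sigmas: [45, 55, 60, 69]
pb210_depth: 32
pb210_flux: 160
supported: 15
pb210_cv: 0.05
cohort:
  n_trees: 20
  establishment_year: 1838
  last_year: 2018
  dbh_target: 5.6
  dbh_sd_frac: 0.20
  growth_k: 0.035
  growth_t0: 55
  width_cv: 0.10
  plot_area: 100
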