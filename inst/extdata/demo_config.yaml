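# Demonstration pipeline configuration: 4 synthetic regions, harvest
# years 2009-2018. Omitted keys keep the package defaults (onset criteria
# 25 mm / 6 d / 0.1 mm / 10 d / 40 d; season length 110 d; GDD base/cap
# 10/30 C; SST leads 120/120/30 d; selection caps 5 and 4).
synthetic:
  n_regions: 4
  years: [2009, 2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018]
  mean_annual_rain: 800
  seed: 20
max_vars: 5
max_vars_level2: 4
r_threshold: 0.7
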