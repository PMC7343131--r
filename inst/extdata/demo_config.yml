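# Demo configuration: a small synthetic fishery with a known 50% reduction
# in bigeye tuna catch rates inside the Kingman/Palmyra treatment zone from
# 2009, evaluated end to end (simulate -> zones -> standardize -> impact ->
# comparisons). Problem sizes are kept small so the full run finishes in a
# couple of minutes on one CPU.
seed: 1
output_dir: demo_out

simulation:
  n_vessels: 25
  years: [1999, 2014]
  sets_per_year: 250
  interventions:
    - species: BET
      zone: kp110
      multiplier: 0.5
      start_year: 2009
      path: step

standardization:
  likelihood: gaussian   # log catch-rate geoGAMM
  k_spatial: 20

impact:
  species: [BET]
  treatment_zones: [kp110]
  intervention_year: 2009
  n_draws: 2000
  burn_in: 500
  threshold: 0.95
  transform: log

comparisons:
  etp_species: [BSH]
  rare_species_set: true
  rare_species: [ALBA, RID, SMA, ODO]
  tlc: true
  shannon: true
  shannon_boot: 200
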