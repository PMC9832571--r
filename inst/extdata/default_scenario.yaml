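plants:
- taxon: cactus_a
  peak_day: 62.0
  peak_sd: 10.0
  peak_abundance: 180.0
  year_shift_sd: 6.0
- taxon: shrub_a
  peak_day: 78.0
  peak_sd: 14.0
  peak_abundance: 420.0
  year_shift_sd: 6.0
- taxon: tree_a
  peak_day: 90.0
  peak_sd: 12.0
  peak_abundance: 260.0
  year_shift_sd: 6.0
- taxon: herb_a
  peak_day: 52.0
  peak_sd: 9.0
  peak_abundance: 90.0
  year_shift_sd: 6.0
- taxon: herb_b
  peak_day: 70.0
  peak_sd: 11.0
  peak_abundance: 120.0
  year_shift_sd: 6.0
- taxon: shrub_b
  peak_day: 84.0
  peak_sd: 13.0
  peak_abundance: 150.0
  year_shift_sd: 6.0
- taxon: herb_c
  peak_day: 98.0
  peak_sd: 10.0
  peak_abundance: 80.0
  year_shift_sd: 6.0
- taxon: herb_d
  peak_day: 108.0
  peak_sd: 12.0
  peak_abundance: 60.0
  year_shift_sd: 6.0
bees:
- taxon: bee_sp1
  mismatch_effect: -0.08
  mean_cells: 12.0
  nests_per_year: 8.0
  nesting_spread: 14.0
  year_shift_sd: 5.0
  cells_resid_sd: 0.3
  year_effect_sd: 0.12
  diet_concentration: 30.0
  pollen_nests: 32.0
  length_measured: yes
- taxon: bee_sp2
  mismatch_effect: -0.05
  mean_cells: 8.0
  nests_per_year: 48.0
  nesting_spread: 14.0
  year_shift_sd: 5.0
  cells_resid_sd: 0.3
  year_effect_sd: 0.12
  diet_concentration: 30.0
  pollen_nests: 51.0
  length_measured: no
- taxon: bee_sp3
  mismatch_effect: -0.03
  mean_cells: 6.0
  nests_per_year: 17.0
  nesting_spread: 14.0
  year_shift_sd: 5.0
  cells_resid_sd: 0.3
  year_effect_sd: 0.12
  diet_concentration: 30.0
  pollen_nests: 18.0
  length_measured: no
- taxon: bee_sp4
  mismatch_effect: -0.013
  mean_cells: 5.0
  nests_per_year: 5.0
  nesting_spread: 14.0
  year_shift_sd: 5.0
  cells_resid_sd: 0.3
  year_effect_sd: 0.12
  diet_concentration: 30.0
  pollen_nests: 8.0
  length_measured: no
- taxon: bee_sp5
  mismatch_effect: 0.0
  mean_cells: 6.0
  nests_per_year: 7.0
  nesting_spread: 14.0
  year_shift_sd: 5.0
  cells_resid_sd: 0.3
  year_effect_sd: 0.12
  diet_concentration: 30.0
  pollen_nests: 14.0
  length_measured: yes
diet:
- - 0.93
  - 0.01
  - 0.01
  - 0.01
  - 0.01
  - 0.01
  - 0.01
  - 0.01
- - 0.02
  - 0.86
  - 0.04
  - 0.01
  - 0.02
  - 0.02
  - 0.02
  - 0.01
- - 0.03
  - 0.12
  - 0.7
  - 0.02
  - 0.06
  - 0.03
  - 0.02
  - 0.02
- - 0.1
  - 0.22
  - 0.16
  - 0.04
  - 0.38
  - 0.02
  - 0.06
  - 0.02
- - 0.18
  - 0.16
  - 0.15
  - 0.13
  - 0.12
  - 0.1
  - 0.09
  - 0.07
n_years: 9.0
first_season: 2006.0
n_sites: 2.0
plots_per_site: 3.0
survey_interval: 7.0
survey_days:
- 28.0
- 35.0
- 42.0
- 49.0
- 56.0
- 63.0
- 70.0
- 77.0
- 84.0
- 91.0
- 98.0
- 105.0
- 112.0
- 119.0
- 126.0
- 133.0
- 140.0
pollen_seasons: 3.0
mask_fraction: 0.7
length_intercept: 10.0
length_slope: 14.0
length_sd: 5.0
resource_threshold: 0.85
pollen_grains: 600.0
seed: 1
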