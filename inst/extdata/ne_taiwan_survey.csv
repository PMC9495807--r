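key,value
n_stations,25
n_species,108
n_copepodite_taxa,13
total_mean_abundance,774.24
total_mean_abundance_sd,289.42
station_total_min,279.08
station_total_max,1510.19
group_A_abundance_mean,952.51
group_A_abundance_sd,278.29
group_B_abundance_mean,838.59
group_B_abundance_sd,238.18
group_C_abundance_mean,552.07
group_C_abundance_sd,246.31
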