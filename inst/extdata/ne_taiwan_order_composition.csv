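order,n_species,mean_abundance,mean_abundance_sd
Calanoida,68,612.95,296.27
Poecilostomatoida,33,130.22,59.81
Cyclopoida,NA,24.31,20.98
Harpacticoida,NA,8.70,8.15
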