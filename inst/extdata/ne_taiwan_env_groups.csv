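group,temperature_mean,temperature_sd,salinity_mean,salinity_sd,do_mean,do_sd,ph_mean,ph_sd
A,22.78,0.58,34.19,0.10,7.07,0.08,8.33,0.03
B,24.31,0.37,34.17,0.03,6.89,0.04,8.36,0.02
C,26.52,0.63,34.27,0.04,6.63,0.07,8.39,0.01
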