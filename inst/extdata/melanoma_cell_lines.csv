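cell_line,alpha0,alpha0_sd,beta0,beta0_sd,repair_rate,repair_rate_sd
HX34,0.263,0.016,0.047,0.005,8.857,2.175
M8,0.612,0.130,0.066,0.020,8.769,2.128
Mel-J,0.002,0.047,0.050,0.009,8.916,2.126
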