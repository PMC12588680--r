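# High-beta mediation model: motor-cortex high-beta power and burst
# amplitude as inputs, the same STN parameters as mediators, predicting the
# cylinder-test score and the histological endpoints.
mcx_high_beta_power -> stn_high_beta_power
mcx_high_burst_amplitude -> stn_high_burst_amplitude
stn_high_beta_power -> cylinder_index
stn_high_burst_amplitude -> cylinder_index
stn_high_beta_power -> th_count
stn_high_burst_amplitude -> th_count
stn_high_beta_power -> striatal_od
stn_high_burst_amplitude -> striatal_od
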