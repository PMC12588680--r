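# Low-beta mediation model: low-beta power from MCx and STN as inputs with
# striatal optical density as the mediator, predicting the cylinder-test
# score and the TH+ neuron count.
mcx_low_beta_power -> striatal_od
stn_low_beta_power -> striatal_od
striatal_od -> cylinder_index
striatal_od -> th_count
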