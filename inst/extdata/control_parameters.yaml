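# Model parameters for the control condition (1.5 mM external calcium),
# in the format accepted by load_model_config(). Concentration-valued
# fields may be plain numbers in molar or {value, unit} pairs.
control:
  priming:
    p_fusion: 0.22
    N_total: 2622
    k1_rest: 0.370
    b1: 0.221
    sigma1: 2.245e+6
    k2_rest: 0.199
    b2: 0.253
    sigma2: 1.014e+6
    tau_TSL: 0.09
    kappa_TSL: 0.1
    b4: 2.6
    ca_rest: {value: 50, unit: nM}
  transient:
    mode: local_plus_global
    amp_global: {value: 454, unit: nM}
    tau_fast: 0.06
    tau_slow: 0.23
    f_slow: 0.15
    amp_local: {value: 30, unit: uM}
    tau_local: 2.5e-04
  influx:
    y_inc: 0.39
    z_dec: 0.4
    y_max: 1.31
    z_min: 0.87
    tau_y: 0.017
    tau_z: 3
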