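# step-stimulus demonstration of the linear plasticity rule
regime: custom
mode: linear
g: step
theta_D: 0.5
eta_D: 0.1
theta_P: 1.0
eta_P: 0.2
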