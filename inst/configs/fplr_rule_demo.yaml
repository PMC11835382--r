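# step-stimulus demonstration of the asymptotic (FPLR) plasticity rule
regime: custom
mode: fplr
g: step
theta_D: 0.5
F_D: 0.0
eta_D: 0.1
theta_P: 1.0
F_P: 1.0
eta_P: 0.1
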