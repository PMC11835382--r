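# frequency-dependent plasticity in a rate model: both pre and post rates
# contribute calcium; use with phase_plane()
regime: custom
mode: fplr
g: linear
b: 0.0
theta_D: 0.5
F_D: 0.0
eta_D: 0.1
theta_P: 0.8
F_P: 1.0
eta_P: 0.1
alpha: 0.3
gamma: 0.0
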