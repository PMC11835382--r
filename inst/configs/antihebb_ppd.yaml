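# reversed-threshold anti-Hebbian "out of sync, wire together" (PPD)
regime: antihebb_ppd
mode: fplr
g: step
N: 10
b: -1.8
theta_D: 0.8
F_D: 0.0
eta_D: 0.1
theta_P: 0.5
F_P: 1.0
eta_P: 0.1
alpha: 0.55
beta: 0.0
gamma: 0.6
delta: 0.0
supervisor: none
init_weights: 0.5
n_timesteps: 100
seed: 7
stream:
  kind: random_binary
  p_active: 0.5
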