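# unsupervised recognition of a repeated signal pattern via heterosynaptic
# depression of inactive synapses and homosynaptic potentiation of active ones
regime: heterosynaptic_unsupervised
mode: fplr
g: step
N: 12
b: -8.0
theta_D: 0.7
F_D: 1.0
eta_D: 0.025
theta_P: 2.6
F_P: 3.0
eta_P: 0.025
alpha: 2.0
beta: 0.2
gamma: 0.0
delta: 0.0
supervisor: none
init_weights: 2.0
n_timesteps: 300
seed: 11
stream:
  kind: signal_noise
  k: 4
  p_signal: 0.5
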