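# perceptron learning with a label ("target") supervisor; requires the
# post-potentiative neutral zone so true positives leave weights unchanged
regime: perceptron_label
mode: fplr
g: step
N: 24
b: -3.0
theta_D: 0.5
F_D: 0.0
eta_D: 0.2
theta_P: 0.6
F_P: 1.0
eta_P: 0.2
theta_PPNZ: 0.8
eta_PPNZ: 0.0
F_PPNZ: 0.25
alpha: 0.45
beta: 0.0
gamma: 0.1
delta: 1.0
Z_P: 0.3
supervisor: label
init_weights: 0.5
n_timesteps: 600
seed: 2
stream:
  kind: classification
  n_patterns: 6
  k: 8
  positive_fraction: 0.5
  epochs: 100
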