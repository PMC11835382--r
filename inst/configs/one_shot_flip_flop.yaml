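# one-shot flip-flop (idealized behavioral-timescale plasticity): a plateau
# supervisory signal writes the binarized input into binary weights at once
regime: one_shot_flip_flop
mode: fplr
g: step
N: 14
b: -6.0
theta_D: 0.5
F_D: 0.0
eta_D: 1.0
theta_P: 0.7
F_P: 1.0
eta_P: 1.0
alpha: 0.2
beta: 0.0
gamma: 0.0
delta: 0.6
Z: 1.0
supervisor: schedule
init_weights: 0.0
n_timesteps: 120
seed: 5
stream:
  kind: circular_track
  n_locations: 4
  k: 7
  n_laps: 30
  n_supervised: 4
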