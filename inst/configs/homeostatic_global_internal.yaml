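# global homeostasis: internal spike-calcium depression plus a disinhibitory
# potentiation supervisor; even synapses start weak, odd synapses strong
regime: homeostatic_global_internalD
mode: fplr
g: linear
N: 20
b: 0.0
theta_D: 0.5
F_D: 0.0
eta_D: 0.02
theta_P: 1.0
F_P: 0.5
eta_P: 0.02
alpha: 0.0
beta: 0.0
gamma: 0.2
delta: 1.0
Z_P: 1.05
supervisor: homeostatic_potentiation_only
y_min_star: 1.0
y_max_star: 3.0
y_max_phys: 5.0
init_weights: [0.45, 0.05, 0.45, 0.05, 0.45, 0.05, 0.45, 0.05, 0.45, 0.05,
               0.45, 0.05, 0.45, 0.05, 0.45, 0.05, 0.45, 0.05, 0.45, 0.05]
n_timesteps: 400
seed: 3
stream:
  kind: even_odd
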