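# shared fixtures: the canonical threshold pairs and the packaged
# parameter-row configs with their learning regimes

th_std <- plasticity_thresholds(0.5, 0.8)
th_wide <- plasticity_thresholds(0.5, 1.2)
th_rev <- plasticity_thresholds(0.8, 0.5)

# packaged config name -> regime, one per simulation-parameter row
row_regimes <- c(
  hebbian_nnp = "hebbian_nnp",
  hebbian_ddp = "hebbian_ddp",
  antihebb_nnd = "antihebb_nnd",
  antihebb_ppd = "antihebb_ppd",
  heterosynaptic_unsupervised = "heterosynaptic_unsupervised",
  one_shot_flip_flop = "one_shot_flip_flop",
  homeostatic_global_internal = "homeostatic_global_internalD",
  homeostatic_targeted_internal = "homeostatic_targeted_internalD",
  homeostatic_global_dual = "homeostatic_global_dual",
  homeostatic_targeted_dual = "homeostatic_targeted_dual",
  perceptron_label = "perceptron_label",
  perceptron_critic = "perceptron_critic"
)

load_row_config <- function(name) load_config(name, validate = "none")

# region ordering for the monotonicity law: outcomes can only escalate with
# calcium (standard: N < D < P; reversed: N < P < D)
region_rank <- function(letters, order) {
  ranks <- if (order == "standard") c(N = 0, D = 1, P = 2) else c(N = 0, P = 1, D = 2)
  unname(ranks[letters])
}
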