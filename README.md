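# calcitron

Synaptic plasticity in the brain is widely held to follow the **calcium
control hypothesis**: the intracellular calcium concentration at a dendritic
spine decides what happens to that synapse — low calcium leaves it alone,
intermediate calcium depresses it, high calcium potentiates it (with the
order reversed in cerebellar Purkinje cells). What that biophysical rule has
to do with the *learning rules* of theoretical neuroscience — Hebbian
plasticity, homeostatic scaling, perceptron learning — is much less obvious.

This package implements the **calcitron**, a perceptron-like neuron model
that closes that gap. The neuron computes

    ŷ = g( Σᵢ wᵢ xᵢ + b )

and every spine receives calcium from four sources, each with its own
coefficient:

    Cᵢ = α·xᵢ  +  β·Σⱼ wⱼxⱼ  +  γ·ŷ  +  δ·Z

— local presynaptic influx, heterosynaptic depolarization, the
backpropagating action potential, and an external supervisory signal `Z`.
Calcium is then mapped to weight changes either linearly (fixed ±η steps) or
through the **FPLR rule** (fixed-point/learning-rate: each calcium region
has a target weight `F` and a rate `η`, and `w ← w + η(F − w)`). Purely by
choosing coefficients and thresholds — and, for supervised regimes, small
supervisory circuits — the same neuron implements Hebbian and anti-Hebbian
learning, frequency-dependent plasticity, unsupervised recognition of
repeated input patterns, one-shot place-field ("flip-flop") learning,
homeostatic rate control, and the perceptron learning algorithm.

The package is aimed at computational neuroscientists who want a tested,
scriptable implementation of calcium-controlled plasticity: typed parameter
records, seeded pattern generators, end-to-end experiment runners with full
per-spine traces, an exhaustive analysis of which pre/post learning rules
calcium control can express, per-regime inequality validators, and a small
CLI.

## Worked example: one-shot place-field learning

A supervisory plateau potential acts as a "write" command: with learning
rates set to 1, the plateau writes the binarized input pattern into binary
weights in a single step, turning the neuron into a place cell for the
location where the plateau occurred.

```r
library(calcitron)

cfg <- load_config("one_shot_flip_flop")
cfg
#> <calcitron_config> regime = one_shot_flip_flop, mode = fplr, g = step, N = 14
#>   thresholds: theta_d = 0.5, theta_p = 0.7
#>   coefficients: alpha = 0.2, beta = 0, gamma = 0, delta = 0.6; b = -6
#>   supervisor: schedule (Z = 1, Z_P = 0, Z_D = 0)

trace <- run_experiment(cfg)          # 30 laps on a 4-location circular track
summarize_trace(trace, "place_field")$events
#>   supervised_step spikes_at_location silent_elsewhere
#> 1              23               TRUE             TRUE
#> 2              54               TRUE             TRUE
#> 3              79               TRUE             TRUE
#> 4             107               TRUE             TRUE
```

Each row is one plateau event: on the lap after every plateau the neuron
spiked at the supervised location and nowhere else, and each later plateau
overwrote the previous place field. The per-spine calcium, plasticity
regions, and weights behind this are all in `trace`.

The rule-space analysis is equally direct. For thresholds
`θ_D = 0.5, θ_P = 0.8` (pre-depressive region wider than the depressive
region), exactly 13 of the 27 conceivable pre/post rule codes are
implementable:

```r
enumerate_feasible_rules(plasticity_thresholds(0.5, 0.8))
#>  [1] "DDP" "DND" "DNP" "DPP" "NDD" "NDP" "NND" "NNN" "NNP" "NPP" "PDP" "PNP"
#> [13] "PPP"

synthesize_coefficients("NNP", plasticity_thresholds(0.5, 0.8))[c("alpha", "gamma")]
#> $alpha
#> [1] 0.44
#>
#> $gamma
#> [1] 0.44
```

The witness pair means: with `α = γ = 0.44`, neither input alone nor a spike
alone reaches `θ_D`, but together they exceed `θ_P` — classic "fire
together, wire together".

## Command line

```sh
Rscript inst/cli/calcitron.R rules --theta-d 0.5 --theta-p 0.8
Rscript inst/cli/calcitron.R validate --regime one_shot_flip_flop --config one_shot_flip_flop
Rscript inst/cli/calcitron.R run --config hebbian_nnp --out out/ --seed 7
```

`run` exports per-timestep and per-synapse CSVs plus an exactly
round-trippable JSON bundle with MD5 manifest; identical arguments produce
byte-identical outputs. Packaged example configs (one per canonical
parameter row, named by regime) are listed by `list_example_configs()`.

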