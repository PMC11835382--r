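---
title: "The calcitron: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The calcitron: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitron)
```

## The model

The calcitron is a perceptron-like point neuron whose synaptic plasticity is
driven entirely by per-spine calcium. At each discrete timestep an input
vector $x \in \mathbb{R}_{\ge 0}^N$ is presented and the neuron computes

$$\hat{y} = g\Big(\sum_{i=1}^N w_i x_i + b\Big),$$

with non-negative weights $w_i$ (excitatory synapses), a bias $b \le 0$
standing in for aggregate inhibition, and $g$ either a step nonlinearity
(spike/no-spike; the neuron fires strictly when the net input exceeds 0) or a
rectifier (a non-negative firing rate). Each spine then accumulates calcium
from four sources:

$$C^{\text{total}}_i
  = \underbrace{\alpha x_i}_{\text{local}}
  + \underbrace{\beta \sum_j w_j x_j}_{\text{heterosynaptic}}
  + \underbrace{\gamma \hat{y}}_{\text{backpropagating spike}}
  + \underbrace{\delta Z}_{\text{supervisor}}.$$

The local term models NMDA-receptor influx at the stimulated spine and is
deliberately *weight-independent*: synaptic strength lives in AMPA
conductance, while the calcium that gates plasticity enters through NMDA
receptors, so potentiating a synapse must not change its sensitivity to
subsequent plasticity protocols (this also avoids a positive-feedback loop).
The three other sources are global: they reach every spine equally, and only
the local term breaks the symmetry between synapses within a timestep. NMDA
voltage dependence is not modelled separately; depolarization-dependent
influx is folded into the heterosynaptic term. The supervisory signal $Z$
never contributes to $\hat{y}$ — downstream neurons see output spikes, not
plasticity plateaus.

Calcium maps to weight changes through two interchangeable rules, gated by a
depression threshold $\theta_D$ and a potentiation threshold $\theta_P$. In
the standard (hippocampal/cortical) order $\theta_D < \theta_P$: calcium
below $\theta_D$ does nothing, calcium in the **closed** interval
$[\theta_D, \theta_P]$ depresses, calcium above $\theta_P$ potentiates. The
Purkinje-style reversed order swaps the middle and upper outcomes.

* **Linear rule** — a fixed step per timestep: $\Delta w = -\eta_D$ in the
  depressive region, $+\eta_P$ in the potentiative region, $0$ otherwise.
  Simple, but unbounded: weights can grow without limit or cross zero.
* **FPLR rule** (fixed-point / learning-rate) — each calcium region has a
  target weight $F$ and a rate $\eta \in [0,1]$, and
  $w \leftarrow w + \eta\,(F - w)$. Weights approach $F$ geometrically with
  ratio $1-\eta$ ($w_t = F + (1-\eta)^t (w_0 - F)$), stay inside the envelope
  of fixed points, and $\eta = 1$ gives switch-like one-step writes. The
  depressive and potentiative fixed points play the role of
  $w_{\min}$/$w_{\max}$.

Defaults follow the conventions of the asymptotic calcium-control
literature: no pre-depressive drift ($\eta_{\text{drift}} = 0$; synapses are
stable at low calcium), and equal depression and potentiation rates
($\eta_D = \eta_P$), with unequal rates supported for the slower kinetics of
LTD. An optional third threshold $\theta_{PPNZ} > \theta_P$ adds a
*post-potentiative neutral zone* — calcium so high that plasticity shuts off
again — whose default behaviour is "no change" ($\eta_{PPNZ} = 0$); it is
only used by the label-supervisor perceptron and is supported only under the
standard threshold order.

### Boundary conventions

The depressive interval is closed at both ends, exactly as the two-threshold
rule is usually written; potentiation starts strictly above $\theta_P$, and
the PPNZ starts strictly above $\theta_{PPNZ}$. For reversed thresholds no
convention is printed anywhere we know of, so the middle (potentiative)
region mirrors the standard convention and is closed at both ends. These
choices matter at measure-zero points only, but the rule-space analysis
below deliberately probes them.

## The rule space

With binary inputs and outputs, a pre/post plasticity rule is a 3-letter
code over $\{N, D, P\}$: the outcome at an active synapse without a spike
(calcium $\alpha$), at an inactive synapse with a spike ($\gamma$), and at
an active synapse with a spike ($\alpha + \gamma$). There are $3^3 = 27$
codes, or $3^4 = 81$ if a fourth "neither" slot were allowed — it is not,
because zero activity yields zero calcium and hence no change.

Because the "both" calcium is the *sum* of the other two, outcomes can only
escalate: in the region ordering ($N < D < P$ standard, $N < P < D$
reversed), the third letter can never rank below either of the first two.
"PPN", for instance, is unimplementable for every threshold pair. Two
scenarios exist per threshold order, depending on whether the middle region
is wider than the region below it: with $\theta_P - \theta_D > \theta_D$
no-penalty Hebbian learning (NNP) is impossible but all-depression (DDD) is
available, and vice versa. Each scenario admits exactly 13 codes; their
union per order is 14. The boundary pair $\theta_P = 2\theta_D$ sides with
the wide scenario because the depressive interval is closed.

The package computes these sets twice, by design: `feasible_rules_analytic()`
does exact interval arithmetic over the region value-intervals (tracking
open/closed endpoints), and `enumerate_feasible_rules()` brute-forces a
coefficient grid that includes the exact threshold values and
$\pm 10^{-9}$ offsets so every boundary convention is exercised. The test
suite requires the two routes to agree across randomized threshold pairs;
`synthesize_coefficients()` additionally returns, for any feasible code, a
witness pair maximally distant from all region boundary lines and verifies
it by round-tripping through `rule_outcomes()`.

## Supervisory circuits

Supervisors are modelled functionally (threshold logic), not as membrane
dynamics:

* **Schedule** — externally timed plateau potentials of magnitude $Z$, used
  for one-shot flip-flop (1SFF) learning.
* **Label** — broadcasts the target label as $Z_P \cdot y$.
* **Critic** — compares $\hat{y}$ to $y$ and emits $Z_P$ on false negatives,
  $Z_D$ on false positives, nothing on correct trials.
* **Homeostatic** — a disinhibitory loop that emits $Z_P$ when the rate
  falls strictly below $\hat{y}^*_{\min}$, optionally paired with a
  depression supervisor emitting $Z_D$ strictly above $\hat{y}^*_{\max}$.
  Outputs exactly at a band edge draw no supervision.

Supervision is computed from the *same* timestep's output and label; since
$Z$ never feeds the output there is no circularity, and the resulting
weight update lands at the next timestep.

`validate_regime()` encodes each learning regime's inequality system and
reports every constraint separately. Three renderings deserve comment:

* The internal-depression homeostatic condition "the maximum physical rate
  must not potentiate" is checked non-strictly,
  $\theta_P \ge \gamma\,\hat{y}_{\max}$: calcium exactly at $\theta_P$ still
  falls in the closed depressive interval, and the canonical global
  parameter set ($\gamma = 0.2$, $\hat{y}_{\max} = 5$, $\theta_P = 1$) sits
  exactly on this boundary.
* The targeted variant's potentiation condition is likewise checked as
  $\delta Z_P + \alpha \ge \theta_P$; with the canonical parameters the sum
  is exactly $\theta_P$, and the strict margin is supplied at runtime by the
  spike calcium $\gamma \hat{y} > 0$ whenever the neuron fires at all.
* The label-supervisor perceptron is validated quadrant by quadrant
  (true/false positives/negatives, active/inactive synapses, each required
  to land in its region). The coarser aggregate inequality
  $\delta Z_P + \gamma > \theta_{PPNZ}$ is reported as an informational row
  only: the canonical parameters satisfy every quadrant while violating the
  aggregate form. Similarly, the critic regime's first supervisor bound is
  checked on $Z_D$ (the depression arm it manifestly concerns).

$\theta_{PPNZ}$ itself is not part of the canonical parameter tables; any
value in $(\delta Z_P + \alpha,\ \delta Z_P + \alpha + \gamma) =
(0.75, 0.85)$ satisfies the quadrants, and the package's packaged config
uses 0.8, the midpoint. This is a package choice, not a tabulated value.

## Protocols and generator defaults

Each packaged configuration reproduces one canonical parameter row; where a
protocol's ensemble statistics are not tabulated anywhere, the generator
default is a fixed package choice, stated here once:

* **Hebbian runs** (`hebbian_nnp`, `hebbian_ddp`, `antihebb_nnd`,
  `antihebb_ppd`): $N = 10$, $b = -1.8$, 100 steps of Bernoulli(0.5) binary
  input per synapse, initial weights 0.5 (the midpoint of $[F_D, F_P] =
  [0, 1]$). Density 0.5 makes chance spikes at $b = -1.8$ frequent enough to
  drive the positive/negative feedback loops the four rules exhibit.
* **Heterosynaptic pattern learning**: $N = 12$, $k = 4$ active synapses per
  pattern — the unique small sparsity satisfying the inequality chain
  $\theta_D < \beta k w_{\min} < \beta k w_{\max} < \theta_P <
  \beta k w_{\min} + \alpha$ with the canonical $\beta = 2/10$, $\alpha = 2$,
  $[w_{\min}, w_{\max}] = [1, 3]$ — signal probability 0.5, 300 steps,
  initial weights 2.0 (initial drive $8 = -b$: no spike, but learnable).
  Noise patterns are pairwise distinct and distinct from the signal.
* **Circular track (1SFF)**: 4 locations, $k = 7$ of $N = 14$, so a stored
  pattern drives $7 > -b = 6$ and fires, while any distinct pattern overlaps
  at most 6 and stays silent. 30 laps, 4 plateau events spaced at least two
  laps apart with a clean lap after each. Plateau timing is idealized to
  same-timestep supervision.
* **Homeostasis**: $N = 20$, 400 steps, even/odd patterns in uniform random
  order; even synapses start at 0.05 and odd at 0.45 within $[0, 0.5]$, so
  the two patterns initially drive $\hat{y} = 0.5 < \hat{y}^*_{\min} = 1$
  and $\hat{y} = 4.5 > \hat{y}^*_{\max} = 3$. The physical ceiling is
  $\hat{y}_{\max} = 5$ (10 active synapses at $w_{\max} = 0.5$).
* **Perceptron**: 6 distinct patterns, $k = 8$ of $N = 24$, half labelled
  positive, initial weights 0.5, presented in fresh random order for 100
  epochs; the per-epoch error count is the convergence diagnostic (errors
  must reach zero and stay there).

All randomness flows from a single per-experiment seed through the
generators; re-running a configuration is bit-identical, and traces
round-trip exactly through the JSON export.

## What the synthetic streams do and do not show

The generators emulate the *logical* structure of the protocols — fixed
sparsity, pattern identity, label balance, plateau timing — with none of the
temporal structure of real spike trains: no calcium decay, no
spike-timing-dependent effects (a single timestep contains an input and the
spike it causes, which is exactly why STDP is out of scope), no dendritic
geometry or location-dependent heterosynaptic falloff, no neuromodulation.
Passing tests therefore certify the calcium-control logic and its parameter
inequalities, not quantitative agreement with slice physiology.

Two behaviours of the running model are worth knowing when reading
summaries. First, in the heterosynaptic protocol the initial drive sits
exactly at threshold, so detection becomes mostly correct within a few
signal presentations, and a steady residual error rate of a few percent
remains at convergence (a noise pattern overlapping the signal at 3 of its
4 synapses can still drive a false positive — visible in the weight
equilibria: signal synapses settle near $7/3$, others near $4/3$). The
early-versus-late correctness improvement is therefore a claim about means
across seeds, and the test suite asserts it as such, while the weight
competition (signal mean strictly above noise mean) holds in every run.
Second, the internal-depression homeostatic mechanisms begin depressing at
$\hat{y} = \theta_D / \gamma = 2.5$, inside the nominal band $[1, 3]$, so
converged outputs occupy roughly $[1, 2.5]$ — comfortably within the band
the acceptance window checks.

## Numerical choices

* Step activation fires strictly above 0; ties do not fire.
* The linear activation clips at 0; with non-negative weights/inputs and
  $b = 0$ the clip never engages, but it documents that rates cannot be
  negative.
* Signed depression rates in parameter tables are normalized to magnitudes
  at load time; the rule applies the sign.
* FPLR iteration matches its closed form to $10^{-12}$ over at least 60
  steps in the tests; the rule-space grid uses $10^{-9}$ boundary offsets,
  far above double-precision noise and far below any threshold spacing.
* Trace JSON uses 17 significant digits so that write/read round-trips are
  exact.

## Problem sizes

The test suite and the acceptance script run entirely on the protocol sizes
above ($N \le 24$, at most 600 timesteps per run, at most 20 seeded
replicates per stochastic claim); the rule-space analysis is exact and
instantaneous at a $\sim 70 \times 70$ coefficient grid. These are the
package's chosen study conditions, matched to the canonical parameter rows.

## Known limitations

No STDP or leaky temporal integration; no NMDA voltage nonlinearity; no
spatial dendrite; no synapse-specific supervisors (ER stores, astrocytes)
— with those, arbitrary rules would be trivially implementable and the
rule-space constraints analysed here would dissolve; single neuron only
(the supervisory microcircuits are modelled as threshold logic, not as
units). Soft-threshold $\eta(C)$/$F(C)$ curves, which would let calcium
titrate the magnitude and not just the direction of change, are noted but
not implemented.
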