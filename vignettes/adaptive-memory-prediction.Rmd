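---
title: "Adaptive memory-prediction hierarchies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive memory-prediction hierarchies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements:
the procedure, its assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and the limitations we
know about. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The memory-prediction loop

The system is a tree of units operated synchronously: one iteration is a
feed-forward (FF) pass of every unit in level order followed by a
feed-back (FB) pass in the reverse order. FF messages are classifications
of the current input; FB messages are predictions of the next one. At the
lowest level the interface vector concatenates sensor values with a
one-hot encoding of the action actually taken in the previous iteration
(state-action pairing, as in SARSA): because the FB output has the same
layout as the FF input, a prediction of the next interface vector *is* a
choice of the next action. Discrete actions are drawn from the motor
slice of the FB output by roulette selection, which keeps exploration
proportional to the model's own uncertainty.

### Spatial pooling

Each unit classifies its input against a 2-d lattice of model vectors
(a Kohonen SOM, trained online with a Gaussian neighbourhood and
exponentially decaying learning rate and radius). The likelihood of model
$i$ is the inverse of the normalized sum of squared errors,

$$A_i \propto \frac{1}{e_i + \beta\,\bar e}, \qquad
  e_i = \lVert w_i - x \rVert^2 ,$$

normalized to total mass 1. The damping term $\beta\,\bar e$ (``smoothing``;
default $\beta = 0$, the undamped form) matters more than it looks: with
$\beta = 0$ an exact-match model produces a numerically one-hot
classification, the transition estimates then contain exact zeros, and —
because predictions enter multiplicatively everywhere — a zero is a veto
no bias can override. A small $\beta$ keeps the response smooth *within*
a cluster of near-duplicate models while leaving between-cluster
contrasts decisive; the word-stream demonstration uses $\beta = 0.3$ for
exactly this reason.

### Bias, orthogonalization, temporal pooling

The classification is multiplied element-wise by the bias cache $B$
formed during the previous FB pass, $P^s \propto A \odot B$, then reduced
to a one-hot (ties break to the lowest row-major index) before entering
the recurrent SOM, whose effective input is the leaky trace
$y_t = (1-\ell)\,y_{t-1} + \ell\,x_t$. With $\ell = 1$ the RSOM is
extensionally a SOM — one of the invariants the test suite checks. The
trace makes temporally adjacent classifications cluster, so RSOM models
come to stand for *sequences*; a decimation knob (`rsom_update_every`)
can slow RSOM learning relative to trace integration, a remedy for the
known weakness that older classifications decay exponentially in the
trace.

### Prediction

A column-stochastic matrix $F$ estimates first-order transition
probabilities between SOM models as recency-biased relative frequencies:
mass leaving state $i$ and arriving at state $j$ between consecutive
biased classifications contributes $\lambda_F\, d_i\, g_j$ to $F_{ji}$
(an outer product when several states shift mass simultaneously), after
which columns are renormalized. The variable-order extension wraps the
first-order core in three topological steps: a centre-excitatory,
surround-inhibitory difference-of-Gaussians sharpens the predictor input
around its winner; elements whose *strong* incoming edges
($F_{ji} > 3/M$) come from priors that were not active are inhibited
through a log-sigmoid of the weight-averaged prior inactivity (an element
whose dominant prior was observed is left untouched; one none of whose
priors were observed is fully suppressed); and the mass lost to
inhibition is reallocated onto grid neighbours of the inhibited cells,
scaled to conserve the lost mass. Because SOM topology places similar
models next to each other, the neighbours are viable alternatives — this
is what lets several near-duplicate models of the same letter specialize
to that letter's occurrences in different words.

### Feed-back

The FB pass inverts the poolers stochastically. An RSOM model is
roulette-selected from the prediction arriving from above and its weight
row (a distribution over SOM states) is perturbed by zero-mean uniform
noise of annealed magnitude $\eta$ and clamped to unit range. That
context $Z$ is combined with the unit's own prediction $P$ as

$$B \propto P \odot Z + \varepsilon/M ,$$

and a SOM model roulette-selected from $B$, again with noise, becomes the
FB output. The uniform term (``bias_floor`` $\varepsilon$) keeps every
model selectable: it is the escape hatch when the two predictions
disagree and the plasticity source once the world is modelled perfectly.
Its weight is a genuine trade-off. Large $\varepsilon$ keeps perception
honest — we observed that with a weak floor the prediction bias can lock
classification into a self-fulfilling loop that ignores observations
outright, which is why the passive pooling demonstrations use a large
floor ($\varepsilon = 5$) — while a small late $\varepsilon$ is required
for near-deterministic exploitation, which is why the game demonstration
anneals it from 0.2 to 0.01.

One deliberate deviation from a uniform-roulette reading: the *topmost*
unit receives an uninformative uniform prior, and inverting that prior
through roulette would manufacture a random sequence context every
iteration. The root unit therefore combines its own prediction with a
flat context instead, which is the stated treatment of the highest layer;
lower units always invert the genuine message from their parent.

## 2. The adaptive components

Reward enters as a single scalar $r \in [0,1]$ per iteration. Because a
bad situation should motivate change regardless of how bad it is, the
system tracks a smoothed reward *derivative*,
$\hat r \leftarrow (1-\alpha)\hat r + \alpha\,\Delta r$, clamped to
$[-1, 1]$. A constant stream drives $\hat r$ to 0 — consistently winning
eventually carries no signal; what persists is the suppression learned
against losing states.

A correlator on each edge holds one correlation value per element of the
relayed FF message, updated only in proportion to each element's
(optionally delayed) activation: $C \leftarrow C + \lambda_C\, y\,(\hat r
- C)$, which keeps $C \in [-1, 1]$. On the FB pass each element is
rescaled by

$$\frac{1 + \theta b}{1 - \theta b}, \qquad b = \operatorname{sign}(C)\sqrt{|C|},$$

and the message renormalized. The signed square root amplifies weak
correlations so they are rapidly tested; the ratio form is linear
($1 + 2\theta b$) for weak bias but unbounded as $\theta|b| \to 1$. The
unboundedness is essential: a bias capped at a constant factor can
reweight a prediction but can never overrule a peaked habitual one, and
in our experiments such a system plateaus near reward 0.7 where the
unbounded form reaches 0.93+. $\theta$ remains the "maximum influence"
dial: the package default is 0.5 and the game demonstration uses 1.

On delays: the sensor-motor convention already lags perception by one
iteration (the hierarchy perceives the previous result while generating
the next), so the FF message at $t$ is the classification of the
action generated at $t-1$ and pairing it with the current $\hat r$ is
already a one-step action-to-reward delay. The `delay` argument counts
*additional* buffered iterations (default 1 for generic use); the game
and bandit configurations use 0, because an extra step would credit a
reward derivative to the state preceding the one that earned it.

## 3. The synthetic worlds

All inputs are generated, seeded, and replayable. The drifting-colour
process advances each RGB channel by a per-channel bias (0.03, 0.01,
0.02) plus Gaussian noise (sd 0.01), wrapping at the unit boundaries.
The moving-lines world emits 4×4 horizontal and vertical line sweeps
separated by 1–4 blank frames; the word stream spells `dad`, `bab`,
`mad`, `dam` as 5×5 binary glyphs with 1–3 blanks between words; the
game opponent cycles rock → paper → scissors, with reward 1/0.5/0 for
win/draw/loss. Glyphs are synthetic fixtures — pairwise distinct, with
the three gesture bitmaps at Hamming distance ≥ 4 — and no result depends
on their exact shapes. Prediction error is the Euclidean distance between
predicted and actual input, divided by its maximum $\sqrt{n}$.

What these worlds do *not* emulate: sensor noise on observations,
non-stationary opponents, continuous action spaces, or rewards delayed by
more than the built-in one-step lag. Passing tests on them shows the
machinery works as specified, not that it scales to natural data.

## 4. Configurations of the four demonstrations

Problem sizes were chosen once, at desk scale. Demo 1: 8×8 SOM on the
3-channel colour process. Demo 2: 5×5 SOM + 3×3 RSOM (leak 0.45) on the
16-pixel line images, with the large bias floor discussed above — this
demonstration reproduces a pure pooling result, so classification is kept
observation-driven. Demo 3: 5×5 SOM + 3×3 RSOM on the 25-pixel letter
images, smoothing 0.3, variable-order predictor (DoG widths 0.5/1.0,
sigmoid gain 10, strong-edge threshold 3/M); 25 models over five symbols
is deliberate capacity pressure — with abundant capacity a first-order
model can dedicate separate states to every context by accident and the
variable-order advantage shrinks. Demo 4: 5×5-SOM and 4×4-SOM units
(no temporal pooling, so the correlator selects moves rather than move
sequences), first-order predictors, one correlator with $\theta = 1$,
$\lambda_C: 0.3 \to 0.05$ over 50k games, noise $1 \to 0.01$ over 10k,
bias floor $0.2 \to 0.01$ over 15k, SOM learning rate $0.25 \to 0.05$ and
radius to 0.3 over 10k. The late learning-rate and radius values keep the
models' motor parts nearly one-hot; a blurrier codebook leaks roughly a
third of the actuator's roulette mass to unintended moves and caps the
attainable reward well below the converged level.

The evaluation of temporal pooling (demo 2) probes the *trained* network
with canonical flushed sequences under frozen learning and records the
winning RSOM model at each sequence end. Labelling raw stream frames
instead conflates class identity with genuine transition clusters — the
first blank frame after a line sweep really is a "transition" pattern,
and a map that represents it has pooled correctly, not failed.

## 5. Numerical choices and degenerate inputs

Grid distributions are plain vectors in row-major order; argmax ties
break to the lowest flat index. All-zero activations fall back to
uniform; an all-zero product in the bias combination leaves the uniform
term alone (so $B$ is always strictly positive); weights are clamped to
$[0,1]$ after every update; roulette selection over a zero-mass vector is
a hard error. Schedules are geometric interpolations with an optional
hold (`lag`) used by higher levels, whose inputs are not well defined
until lower units have learned. Checkpoints serialize every weight
matrix, schedule position, correlation matrix, delay buffer, and RNG
stream to JSON, and a restored hierarchy continues bit-identically.

## 6. Known limitations

* **Fully self-determined states defeat the adaptive loop.** In a
  two-armed bandit — where the interface vector contains nothing but the
  agent's own previous action — the sequence predictor is also the
  policy, and the pair lock into a stable win-lose alternation that the
  multiplicative bias cannot break; the preferred-action frequency
  settles near 0.65, clearly above chance but short of full convergence.
  The game demonstration converges because the opponent's gesture is an
  exogenous anchor: prediction has a reward-free dimension to be good at,
  and the bias only has to choose among moves. This is an architectural
  property worth knowing: the correlator needs valid, externally
  grounded messages to promote or suppress.
* **Derivative reward is blind to constant failure.** A state visited
  only under constant reward loses its correlation; escape from such
  plateaus rests entirely on the uniform floor and the exploration noise.
* **The baseline (no-correlator) agent is not uniform.** Without reward
  pressure the prediction loop crystallizes an arbitrary deterministic
  habit; its moving-average reward wanders around 0.5 but its final
  window — and its action frequencies — are a lottery across seeds. Any
  claim about "chance-level play" is therefore made about the mean of the
  moving-average series, and claims about bias neutrality are made about
  the correlation matrix itself.
* The RSOM trace discounts older classifications exponentially, limiting
  sequence length; decimation mitigates but does not remove this.
* Single-seed paired comparisons of first- vs variable-order prediction
  carry residual seed-to-seed variance in the first-order baseline
  (roughly ±0.02 in normalized error); the advantage is consistent but
  not enormous at these problem sizes.
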