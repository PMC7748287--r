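---
title: "Planning while learning: a spiking winner-take-all world model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning while learning: a spiking winner-take-all world model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spikeplan` simulates an agent that must *learn a world model and use it
for planning at the same time*.  The world model is a discrete-time
spiking neural network organised as a neural hidden Markov model:

* an **input layer** of 10 units — 3 colour stimuli, 5 actions, 2
  feedback outcomes — that observes the environment;
* an **associative layer** of `K = 400` recurrently connected units
  (no self-connections) encoding the hidden causes of the observations
  and their temporal dependencies;
* an **output layer** with the same 10-unit layout as the input,
  generatively reconstructing observations from the hidden causes;
* a **goal layer** of 2 units ("obtain correct feedback" / "obtain
  incorrect feedback") that conditions the associative distribution.

At every discrete step each free-running layer computes membrane
potentials

$$\hat u_k(t) = \sum_i w_{ki}\,s_i(t-1) + \sum_g w_{kg}\,s_g(t-1) +
  \sum_a w_{ka}\,s_a(t-1),$$

subtracts a refractory term $r_0 e^{-t'/\tau_r}$ ($t'$ = steps since the
unit's own last spike; $r_0 = 1.1$, $\tau_r = 9.5$), adds Gaussian noise
(sd $\nu$), and emits **exactly one spike** sampled from the
winner-take-all softmax of the potentials.  The softmax abstracts
lateral inhibition: the layer's total firing is constant and the spike
samples a categorical distribution over the layer's units.

A **planning cycle** runs this network forward for `T = 15` steps with
the observed colour clamped for the first 5 steps and the goal unit on
throughout.  The associative spikes trace a simulated
colour–action–feedback sequence; the output unit that fires most within
each category is read out as the simulated action and predicted
feedback.

### Learning

The world model learns *unsupervised*, only from experienced trials.
Each trial is replayed for 15 steps with the input clamped to the
observed colour, action and feedback in equal thirds, the output layer
teacher-forced to the same schedule, and the associative layer
free-running.  Every spike triggers the STDP rule

$$\Delta w_{post,pre} = \zeta\, s_{post}(t)\,
  \bigl(e^{-w_{post,pre}}\, s_{pre}(t-1) - c\bigr),$$

which potentiates connections from units active one step earlier
(towards the fixed point $w^\ast = -\ln c$) and depresses all others by
$\zeta c$.  This carves chain-like assemblies: groups of associative
units that fire in sequence for each experienced
colour–action–feedback episode, with branch points wherever the same
colour was followed by different continuations.  Goal conditioning uses
a separate bounded reinforcement rule

$$\Delta w_{kg} = \eta\, m\, ET_k\,
  \frac{w_{max} - |w_{kg}|}{w_{max}}\, s_g, \qquad w_{max} = 0.5,$$

with pseudo-reward $m = -1$ applied to the fired units of every failed
planning cycle and $m = +1$ only after actual goal achievement in the
environment.

### Arbitration

After each planning cycle the agent computes the mean normalized
entropy of the associative sampling distributions,

$$H = \frac{1}{T}\sum_t \frac{-\sum_k p_t(k)\ln p_t(k)}{\ln K} \in
  [0, 1],$$

and compares it with a threshold $H_{Th}(f) = \epsilon - f\,\delta$
that starts each trial at $\epsilon$ and drops with every failed cycle
$f$.  Three modes follow: *replan* (confident but the predicted outcome
misses the goal), *act* (confident and goal-matching), *explore*
(too uncertain — a two-layer softmax selector picks the action, and is
punished, never rewarded, when the executed action fails: inhibition of
return).  The number of planning cycles executed is the model's
reaction time.

## Parameters

| name | meaning | range | default (fitted) |
|------|---------|-------|------------------|
| `zeta` | STDP learning rate | 0.1–1 | 0.96 |
| `stdp_c` | STDP depression constant | 0.1–1 | 0.67 |
| `eta` | reinforcement learning rate | 0.001–1 | 0.008 |
| `temperature` | WTA softmax temperature | 0.01–0.1 | 0.02 |
| `noise_sd` | potential noise sd | 0.01–0.1 | 0.02 |
| `epsilon` | initial entropy threshold | 0.3–1 | 0.74 |
| `delta` | threshold decrement per failure | 0.01–0.2 | 0.12 |

Fixed constants: `n_assoc = 400`, `n_steps = 15`, `clamp_steps = 5`,
`r0 = 1.1`, `tau_r = 9.5`, `w_max = 0.5`, 20 triplets per goal phase,
`max_cycles = 50` (a pure safety net: the linear threshold schedule
terminates a trial after at most $\lceil\epsilon/\delta\rceil = 7$
failed cycles).

## Design choices

Several points are genuinely open in the model description; the package
resolves them as follows, and exposes the relevant switches on
`model_params()`.

**Where the softmax temperature acts.**  The parameter table lists a
softmax temperature among the seven fitted parameters, yet the layer
competition formula is written without one, and the exploration
component is said to reuse "the same softmax".  We apply the
temperature to *every* winner-take-all softmax — associative, output
and exploration — i.e. $p_k \propto e^{u_k/\tau}$.  This is the only
reading under which the fitted values are mutually consistent: the STDP
ceiling $-\ln(0.67) \approx 0.40$ becomes a 20-nat discrimination at
$\tau = 0.02$, so learnt chains dominate sampling and the cycle entropy
can actually cross $\epsilon = 0.74$; the small reinforcement step
$\eta = 0.008$ becomes a meaningful 0.4-nat log-odds shift, so goal
biasing and inhibition of return act within a handful of trials; and
the refractory amplitude $r_0 = 1.1$ becomes an effectively absolute
within-cycle refractory, which is what forces distinct units to take
turns and chains to form.  With the temperature confined to the
exploration component, the associative softmax over 400 units stays
within a few percent of uniform for the whole session (measured mean
normalized entropy ≈ 0.97), planning never engages, and none of the
behavioural phenomena emerge.  The core layer mechanics
(`competitive_distribution()`, `step_layer()`) remain temperature-free;
the scaling is applied by the world-model and exploration call sites.

**Timing.**  The drive a layer receives at step $t$ is the source
activity persisting from the end of step $t-1$; clamped input and goal
patterns are constant across the step boundary, so the colour drives
the associative layer on steps 1–5 exactly.  The output layer is driven
by the *previous* step's associative spike, matching the learning
rule's pre-synaptic timing.  At $t = 1$ there is no previous
associative spike: the recurrent and associative→output STDP updates
are skipped (updating a whole column against an all-zero pre vector
would inject a spurious depression once per trial), and the output
layer free-samples from its noise/refractory-only distribution.

**Teacher forcing.**  During learning the output layer is clamped to
the observed events; STDP needs defined post-synaptic spikes and the
ground truth is the natural choice.  During planning it free-samples.

**Refractory semantics.**  The decaying subtraction is indexed from
each unit's own last spike; units that never fired get none.  Ages are
reset at the start of every cycle and replay (each is an independent
forward-sampling run).

**Goal clamping.**  The goal unit is on during both planning and the
learning replay (switchable via `goal_in_learning`), so the goal term
of the potential is defined in both phases; only the reinforcement
rule — never STDP — touches goal weights.  Potential noise is applied
in both phases by default (`noise_in_planning`, `noise_in_learning`).

**Initial weights.**  All trainable matrices start at 0 plus Gaussian
jitter (sd 0.01) to break symmetry; a zero-mean start keeps
$e^{-w} > c$, so potentiation is possible from the first trial.

**Arbitration boundary.**  $H = H_{Th}$ counts as "too uncertain"
(explore); the first cycle of every trial compares $H$ against
$\epsilon$ itself, so reaction times are always $\ge 1$ and bounded by
$\lceil\epsilon/\delta\rceil + 1$.

**Eligibility after explored successes.**  When a successful action
came from exploration there is no successful planning cycle; the
$m = +1$ update uses the fired units of the learning replay, the only
trace guaranteed to contain the executed sequence.

**Staircase designation.**  The designating response is itself declared
correct whatever button was pressed — the only reading under which the
protocol's response-count arithmetic (first success at the 2nd/4th/5th
response for S1/S2/S3) is exact.  In the second goal phase the
established contingencies persist; "achieve an incorrect feedback"
means pressing any non-established action.  Fitting
(`fitness()`) uses phase-1 curves only, since the reference experiment
had only the correct-feedback goal.

## What the synthetic pieces do and do not show

The task environment generates all stimuli internally; no external data
are needed.  `synthetic_reference()` builds reference curves from the
ideal-agent protocol (step functions at the designation trials, an
inverted-U reaction-time template) plus noise.  It exists so that the
fitting harness (`fitness()`, `parameter_search()`) can be exercised
end-to-end and is clearly *not* human data: correlations against it
say nothing about humans, only that the harness wires model curves to
reference curves correctly.  To fit real data, supply your own table
in the same format.

Likewise, passing behavioural tests shows that the *model* reproduces
its stated phenomena (learning-curve rise, inverted-U reaction times,
exploration-first trials, goal-switch recovery with a transient
reaction-time spike) under the fitted parameters — not that those
parameters are uniquely right, nor that the phenomena quantitatively
match any particular participant sample.

## Numerical choices and problem sizes

Probabilities are computed with max-subtracted exponentials (softmax is
shift-invariant); distributions are validated to sum to 1 within 1e-9
at the sampling interface.  Entropy uses the $0\ln 0 = 0$ convention.
Ties in the readout are broken uniformly at random; there is no argmax
path in the sampling core.  All randomness flows through R's RNG, and a
session is a pure function of `(params, seed)`; cohort seeds are
derived as `seed * 1000 + participant`.

The package's own test battery runs cohorts of 20 simulated
participants through both 60-trial goal phases for the behavioural
properties (about half a minute), 400 goal-off planning cycles for the
branching property, and reduced 100-unit associative layers where only
protocol-level behaviour is at stake.  The full parameter search is
supported (checkpointable by combination index, deterministic
per-combination seeds) but a desk-scale run should use tens to
hundreds of combinations rather than the exhaustive campaign.

## Known limitations

* Discrete time and one spike per layer per step; no continuous-time
  (inhomogeneous Poisson) variant.
* The arbitration mechanism is algorithmic, not neural.
* No habit-learning pathway; exploration is punishment-only by design.
* Single-trial planning horizon (one colour–action–feedback
  simulation); the readout handles one action and one outcome per
  cycle.
* Reaction times are in planning cycles, not seconds.
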