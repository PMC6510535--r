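---
title: "Novelty, salience and preference: the models behind aimaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Novelty, salience and preference: the models behind aimaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimaze)
```

## The generative model

`aimaze` simulates discrete-state partially observable Markov decision agents.
A trial of length $T$ produces observations $o_1,\dots,o_T$ caused by hidden
states $s_1,\dots,s_T$. The agent's generative model consists of

* an **observation model** $A$ with $P(o \mid s) = \mathrm{Cat}(A_{\cdot s})$,
  held as Dirichlet concentration parameters $a$ (`observation_model()`), so
  the agent can be *uncertain about the mapping itself*;
* action-conditioned column-stochastic **transition matrices** $B_u$;
* **log preferences** $\tilde c$ over outcomes, authored as raw
  log-expectations and log-softmax normalised (`log_preferences()`);
* a Dirichlet **initial-state prior** $d$;
* a **policy set** $\pi$, fixed action sequences of length $T-1$;
* **precisions** $\gamma = 1/\beta$ (policy selection) and $\alpha$ (action
  selection).

State inference is exact Bayesian filtering under the expected
log-likelihood $\overline{\ln A}_{os} = \psi(a_{os}) - \psi(\sum_{o'}
a_{o's})$ (`bayes_update()`). At the shallow horizons used here ($T \le 3$,
tree-structured dependencies) exact filtering is the fixed point of the
variational scheme these models are usually solved with, so nothing is lost
by not iterating message passing; the test suite verifies that the
variational free energy $F = \mathrm{KL}[Q \| P] - E_Q[\overline{\ln A}_{o\cdot}]$
is minimised by, and equals the negative log evidence at, the filtered
posterior.

## Expected free energy and its three terms

A policy $\pi$ is valued by its expected free energy accumulated over the
remaining trial, $G(\pi) = \sum_\tau G(\pi, \tau)$, with

$$G(\pi,\tau) = -\underbrace{\text{novelty}}_{\text{about } A}
               -\underbrace{\text{salience}}_{\text{about } s_\tau}
               -\underbrace{\text{utility}}_{\text{preferences}}$$

* **Novelty** is the expected information gain about the observation model:
  $\sum_{o,s}\bar o(o)\, W_{os}\, \bar s(s)$ over learnable entries, with the
  inverse-count weights $W_{os} = \tfrac12 (1/a_{os} - 1/\sum_{o'} a_{o's})$.
  This is the standard computable surrogate for the expected Dirichlet KL
  divergence; the test suite audits its sign, ordering over count scales and
  asymptotic decay against the exact KL computed from log-gamma functions.
* **Salience** is the mutual information between predicted states and
  outcomes, $H[\bar o] - \sum_s \bar s(s) H[A_{\cdot s}]$ — the entropy of
  predicted outcomes minus the expected ambiguity.
* **Utility** is the expected log preference $\bar o \cdot \tilde c \le 0$.

All quantities are in nats. Policies are scored by
$Q(\pi) = \sigma(-\gamma G(\pi))$, actions by sampling
$\sigma(\alpha \ln P(a))$ from the policy-marginal action distribution
(`select_action()`; ties at $\alpha \to \infty$ go to the lowest action
index). $\gamma$ is held at its expected value $1/\beta$ throughout a
simulation; trial-wise precision updating is out of scope. Policies are
re-evaluated at every timestep conditioned on the observations so far, with
the policy set restricted to sequences consistent with the actions already
taken — this is what lets a cue observation redirect the subsequent arm
choice within a trial.

Learning accumulates Dirichlet counts at the end of each trial:
$a \mathrel{+}= \eta \, (o \otimes s_{\text{post}})$ on learnable entries
(`update_observation_counts()`), and analogously $d \mathrel{+}= \eta_d \,
s_1^{\text{post}}$ for the initial-state prior. For models with a static
context factor the initial-state posterior is reconstructed from the final
context marginal, which is exact because contexts never change within a
trial.

## Within-trial preference timing

The time profile of the utility term is a genuinely open design choice: the
tasks' preference vectors describe where the agent expects to end up *at the
end of a trial*, but intermediate outcomes cannot be entirely free or
information gathering would have no opportunity cost. `aimaze` uses a
geometric ramp (`pref_timing = "ramp"`): the utility at future step $\tau$
is weighted by $4^{\tau - T}$, i.e. full weight at the trial's end and
quarter weight one step earlier. The two extremes are both inconsistent
with the behavioural phenotypes the package reproduces: with full per-step
preferences, visiting the cue in the context-inference maze forgoes 2 nats
of utility against the safe arm — more than the maximal $\ln 2$ context
salience — so a cue-sampling agent could not exist; with terminal-only
preferences the cue is entirely free, so agents without any epistemic drive
would still drift to it, and cue sampling would never decline as the context
prior sharpens. The quarter-weight ramp keeps the cue's opportunity cost
(0.5 nats) strictly inside the informative range $(0, \ln 2)$ and is fixed
once for all simulations. `pref_timing = "final"` and `"all"` remain
available for sensitivity analyses.

## The three tasks

**Reward learning** (`make_learning_model()`, `tmaze_learning_env()`): three
states, four outcomes, one action per trial ($T = 2$). The safe arm pays one
pellet with certainty; the risky arm pays four pellets with probability
`p_high`. Deterministic mappings are encoded as large fixed counts (512
times the emission probability) with the learnable mask off, so their
novelty is numerically zero and they never update; the risky arm's two
reward outcomes start at concentration 0.25 each. Preferences are
$c = (0, 2, 4, -2)$, $\beta = 1$, $\alpha = 4$, $\eta = 0.5$ unless a
simulation varies them.

**Context inference** (`make_inference_model()`, `tmaze_inference_env()`):
four locations crossed with two contexts (eight states), $T = 3$, four
policies — safe-then-stay, risky-then-stay, cue-then-safe, cue-then-risky.
The cue deterministically signals whether the risky arm rewards with
probability 0.75 or 0.25; the initial prior is certain about the start
location and uniform over contexts (context counts 0.5/0.5). The arms are
absorbing and the trial's reward draw is made once (re-observing an arm
repeats it and yields no further pellets); the agent's model treats the
repeat as an ordinary draw, since classic expected free energy cannot
represent within-trial outcome correlation — for learnable-$A$ agents an
arm trial therefore contributes two count increments. $\alpha = 16$ in the
single-task simulations. The observation space is padded with a seventh,
never-emitted outcome at zero preference so that the model's printed
dimensions (7 outcomes × 8 states) carry one reserved slot; it is inert in
every computation. By default the observation model is fully known here and
the context prior $d$ is *not* learned; `learn_d = TRUE` enables the
cross-trial prior updates used in stable-context experiments.

**Information preference** (`make_info_model()`, `info_preference_env()`):
two offers with equal reward probability 0.5 and configurable pellet
amounts; the informative offer reveals the reward identity during the
delay, the other shows a blank. Reward utility is linear at 0.4 raw
preference units per pellet, so a four-pellet reward matches the high-reward
preference of the maze tasks, and the no-reward outcome sits at 0.
`run_info_preference_sweep()` evaluates the exact first-action probability
per amount pair (the first-step distribution is deterministic, so sampling
would only add noise; finite `n_reps` is available). Under a constant
$\beta$ the informative-offer preference is constant along the equal-amount
diagonal; under the offer-dependent schedule $\log_2 \beta$ falls linearly
from $+1$ at 0 total pellets to $-1$ at 20, making the preference grow with
the stakes. The information bonus is modelled as salience by default, with
a novelty variant (`bonus = "novelty"`) that instead makes the signal
mapping learnable.

## Agent kinds and comparisons

`agent_config()` maps one-to-one onto the ablation flags: the
parameter explorer keeps novelty + utility, the state explorer keeps
salience + utility, the random agent utility only. In comparisons all
agents share $\beta = 1$ and $\eta = 0.5$; goal-directed agents use
$\alpha = 8$ and the random agent $\alpha = 1$. The state explorer runs
without observation-model learning (it is the "no parameter learning"
phenotype) and, in the inference task, with the known context-conditional
observation model; the parameter explorer and the random agent instead get
learnable risky-arm mappings there (priors 0.25), since parameter
exploration is only meaningful when something can be learned. The
stable-context comparison is run under the high-reward context: in the
stable low-reward context every agent converges on the safe arm and the
goal-directed/random ordering carries no signal.

## What the synthetic tasks do and do not emulate

The environments implement exactly the study conditions: true reward
probabilities, context schedules (uniform redraw per trial, or fixed), and
pellet values (1 for the safe, 4 for the high reward). They do not emulate
spatial structure, delay periods, motivational drift, or any within-session
non-stationarity beyond the context schedule — so passing tests show that
the *decision architecture* produces the expected exploration phenotypes
under ideal Markovian conditions, not that real animals are fit by these
parameters. Model fitting to empirical choice data is explicitly out of
scope.

## Numerical choices

* Structural zeros in emission columns are floored at $10^{-16}$ before
  digamma; floored entries are never learnable and vanish under
  normalisation. An observation that is impossible under the current prior
  raises an error naming the outcome rather than renormalising silently.
* Known mappings use fixed counts of 512 × probability. The value is a
  convention, exposed through the constructors' count matrices: large
  enough that residual novelty and digamma bias are far below every
  tolerance used in the tests, small enough to stay well-conditioned.
* Softmaxes subtract the maximum before exponentiation; mutual information
  is clipped at zero against rounding (it is mathematically non-negative).
* Batch runs draw one sub-seed per experiment from the master seed, so any
  experiment can be replayed bit-identically in isolation.
* Problem sizes follow the study conditions: 32-trial experiments; 1000
  experiments for choice-rate curves and the concentration heatmap; 100 for
  cumulative-pellet comparisons; 200 replicates for ablation orderings and
  parameter recovery.

## Known limitations

* Precision $\gamma$ is fixed at $1/\beta$; no within-trial precision
  dynamics, hence no dopamine-style prediction-error readout.
* Transition matrices and the state-space structure are never learned, and
  counts never decay or forget.
* The novelty weight is the standard inverse-count approximation to the
  expected Dirichlet information gain; it matches the exact quantity in
  sign, ordering and limit but not in absolute value.
* Horizons beyond $T = 3$ are supported by the evaluation code but
  untested; no information discounting over deep horizons is implemented.
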