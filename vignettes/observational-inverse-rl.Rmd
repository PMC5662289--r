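---
title: "Observational learning of hidden reward distributions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observational learning of hidden reward distributions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsirl)
```

## The task and why it is hard

An observer watches another agent repeatedly choose between pairs of three
slot machines. Each machine pays out one of three food items under fixed,
hidden probabilities; the agent sees its outcomes, the observer never does.
On a third of the trials the observer chooses for themselves — again without
feedback. The only usable information is the agent's *choices*, plus prior
knowledge of the agent's food preferences, which may align with the
observer's ("similar" agent) or oppose them ("dissimilar"). Copying a
dissimilar agent is self-defeating: the observer must instead invert the
problem — infer which outcome distributions would make the agent's choices
sensible, then evaluate those distributions under their *own* preferences.
That inversion is inverse reinforcement learning (inverse RL), and the
package implements it together with the imitation-based alternatives it is
compared against.

Each session has 150 trials — 100 agent observations and 50 self-choices —
with the three unordered machine pairs balanced within each trial kind.
Outcomes are indexed throughout by the *agent's* preference rank (column 1
of the probability matrix is the agent's favourite food), and preference
values default to 3, 2, 1 over an actor's ranks.

## The simulated agent

The observed agent is itself a simple learner, not a human: machine values
start flat at 1/3, a pairwise softmax with intensity `beta_agent` picks one
of the two displayed machines, and the chosen machine's value moves toward
the revealed outcome's scalar code (1–3 with increasing preference) by a
fraction `alpha`. The 1/3 initialization sits below the attainable outcome
range 1–3; that mismatch is part of the stated procedure and is preserved
deliberately. The agent is identical in both conditions — only the
observer's relation to it changes. The defaults `alpha = 0.3`,
`beta_agent = 3` are our choice (the procedure fixes neither); they produce
the clear best > mid > worst choice-ratio ordering that makes the agent
worth learning from, and both are configurable.

The default outcome-probability matrix is likewise a package choice, since
only its qualitative shape is prescribed:

```
            best outcome  mid  worst      (agent's ranks)
machine 1          0.6    0.3    0.1
machine 2          0.3    0.4    0.3
machine 3          0.1    0.3    0.6
```

It gives each actor an unambiguous best/mid/worst machine in their own
preference space and equal expected-value gaps for the agent.

## Observer models

**Approximate inverse RL.** The observer tracks a 3×3 matrix of
posterior-mean outcome probabilities, one row per machine, initialized
uniform. Seeing the agent choose machine `c` over `u` multiplies row `c`
elementwise by updating constants `eps = (eps1, eps2, eps3)` in (0, 1) and
row `u` by the reversed vector, each followed by renormalization to the
simplex; the unoffered machine's row is untouched. Renormalization is our
resolution of an under-specified step: without it the rows stop being
probabilities. A consequence worth knowing: scaling all three constants by a
common factor cancels exactly, so only the *ratios* of the eps are
identified — relevant both to interpreting fitted values and to how recovery
is scored (below). Machine values are beliefs weighted by preference values;
self-choices use the observer's own values, mapped through the
outcome-identity correspondence (identity when similar, reversal when
dissimilar — arbitrary permutations are supported), and a pairwise softmax
with intensity `beta`. Two trial-wise signals are exported per observation:
the agent-referential expected value of the chosen and unchosen machine
(beliefs × the *agent's* values, at choice time) and the KL divergence, in
nats, from the chosen machine's prior row to its posterior row —
`D_KL(posterior || prior)`, in that order. An optional integer forgetting
window (`decay`, 1–100 trials, disabled by default) restricts beliefs to the
most recent observations; no model variant is singled out as carrying it, so
it is off unless requested.

**Imitation RL.** Values start at 0.5 per machine and the chosen machine
moves toward 1 by prediction error with rate `eta`; no outcome inference at
all. On self-choices an inversion parameter `theta` in [0, 1] blends the
learned value with its complement — `theta = 0` copies the agent,
`theta = 1` anti-copies, `theta = 0.5` erases all information. The
counterfactual variant also decays the unchosen machine toward 0 with its
own rate `eta_unchosen`.

**Preference-ranking learner.** Tracks a distribution over the six strict
orderings of the machines, updated by Bayes rule with a softmax likelihood
of sharpness `kappa` on rank scores (4 − rank), and chooses by softmax on
belief-averaged scores, oriented by the condition (+1 similar, −1
dissimilar). The source description of this model is two sentences; the
score function, likelihood and orientation are our construction, and the
orientation is deliberately condition-set rather than fitted, leaving
`kappa` and `beta` as its two free parameters.

## Fitting, BIC and group-level selection

Only the 50 self-choices carry likelihood; agent trials drive the model
state. Fits minimize the negative log-likelihood under box constraints
(`theta`, `eta` in [0, 1]; `beta` in [2, 22]; `eps` in (0, 1); `decay`
candidates iterated as integers) with `optim(method = "L-BFGS-B")` from
three random starting points inside the box, matching the stated procedure;
per-trial likelihoods are floored at 1e-12 so extreme `beta` cannot produce
infinite objectives (the floor is far below any probability reachable inside
the box, so optima are unaffected). One deviation: the rank learner's
`kappa` starts are drawn log-uniformly, because uniform draws usually land
where the belief has already saturated and the likelihood is numerically
flat, stranding the optimizer at its starting point.

BIC is `2·NLL + k·ln(50)` with `k` the raw number of fitted parameters
(4, 3, 4 and 2 for inverse RL, imitation, counterfactual imitation and the
rank learner), and `-BIC/2` approximates the log model evidence passed to
random-effects model selection. We considered charging inverse RL only 3
effective parameters on identifiability grounds, but the raw count is what
the fitting procedure states and is the convention users will expect;
the identifiability fact is instead absorbed into how recovery is measured.

Random-effects model selection treats the model identity as a random effect
with a uniform Dirichlet prior over population frequencies. At group scale
the posterior is obtained by the standard variational fixed-point iteration
and exceedance probabilities by Monte-Carlo sampling of the Dirichlet
(100,000 samples by default). At very small group sizes the variational
posterior is measurably overconfident, so whenever the per-subject
assignment space is enumerable (`n_models^n_subjects <= 2048`) the exact
mixture-of-Dirichlets posterior is computed instead; tests check it against
an independently coded enumeration oracle.

## Behavioral metrics

Choice ratios divide a machine's choice count by its presentation count for
a given chooser (machines never offered are undefined, not zero — so a
random chooser sits at 0.5, not 1/3). Ratios are reported in *referential
spaces*: machines ordered by the expected value they carry for the relevant
actor, with ties broken by machine label. The cohort-level agent–observer
Spearman correlation pools subject × machine pairs — the unit of analysis is
unstated in the source, and pooling is our choice — and conditions are
compared by Fisher transform with a one-tailed normal test. Plateau ratios
default to trials 76–150, the session's second half; the plateau criterion
is likewise unstated and the cutoff is configurable.

The SI index operationalizes "the entropy between" the two choice-ratio
distributions as a base-2 Jensen–Shannon divergence between the two
normalized, own-space-ordered ratio vectors, inverted: `SI = 1 − JSD`. JSD
is chosen over raw KL because it is symmetric and bounded in [0, 1], which
matches the stated anchors (1 for matching behavior, 0 for mimicking a
dissimilar agent); the exact measure behind the original index is not
specified, so this is a flagged decision rather than inferred intent.

## The synthetic cohort

`generate_cohort()` replaces deposited human data for all tests: 43 subjects
by default, each playing one similar and one dissimilar 150-trial session
against a freshly simulated agent, with observer behavior generated by a
named model whose parameters are drawn per subject — eps components uniform
on (0.05, 0.95), `eta` and `theta` uniform on (0, 1), `beta` uniform on
(2, 22), spanning the fitting boxes without informative bias. Ground-truth
parameters are stored with every session, and all randomness descends from
one master seed.

What the generator does *not* emulate: human preference nonlinearity (the
simulated observer's values over its own ranks are exactly linear),
session-order and fatigue effects, lapses, and any learning of the agent's
preferences themselves (the condition is known, not inferred). One
consequence is worth spelling out. For a fixed agent log, the dissimilar
observer's self-values are exactly `4 −` the similar observer's, and a
pairwise softmax depends only on value differences — so the generative model
is condition-symmetric up to the agent's own learning transient. The
human asymmetry in which best-machine performance is preserved while the
worst machine is specifically over-chosen under dissimilarity is therefore
not a property this generator can reliably reproduce; it plausibly rides on
nonlinear preferences, which inverse RL's free updating constants can absorb
when fitting real subjects but which a linear-value simulator does not emit.
Passing tests on synthetic cohorts certify the estimation machinery, not
that human data would show any particular pattern.

Similarly, parameter recovery from 50 binary self-choices has hard
information limits: the normalized eps spread `(eps1 − eps3)/(eps1 + eps2 +
eps3)` (scale-invariant, hence actually identified) and `theta` recover
well, but `eta` and `beta` trade off through the product of intensity and
value separation, and `theta` near 0.5 erases the information `eta` and
`beta` would need. Recovery checks should be read with those limits in mind.

## Numerical choices and problem sizes

Simplex rows are validated to 1e-8; belief positivity is guaranteed by
eps ∈ (0, 1). Expected-value ties in referential ordering break by machine
label with a message. Exceedance probabilities use 100,000 Monte-Carlo
samples (standard error ≲ 0.002). Test suites use 100 synthetic subjects per
model for parameter recovery, 30 subjects per generator for model-recovery
confusion, 43-subject cohorts for behavioral metrics, and 10,000-update
sweeps for simplex conservation; the acceptance script uses the same sizes.
Multistart fitting is deterministic given its seed, and every simulated
artifact is reproducible from the master seed that produced it.

## Known limitations

The fully Bayesian inverse-RL observer (posterior over hidden outcome
sequences) is out of scope by design — its integrals over outcome sequences
are intractable, which is exactly why the approximate multiplicative scheme
exists. The rank learner is a minimal reconstruction from a brief verbal
description. BIC-based evidences make group-level selection sensitive to
parameter counts when likelihoods tie: on uninformative data the penalty
difference between inverse RL (k = 4) and imitation (k = 3) decides every
subject the same way, and with 30 subjects the group exceedance probability
saturates — an inherent property of penalty-based evidences, not of the
data. Neural analyses are out of scope; the exported trial signals are the
package's endpoint.
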