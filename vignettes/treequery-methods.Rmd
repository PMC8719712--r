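---
title: "Models and methods behind treequery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind treequery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treequery)
```

## The task

An agent faces a binary decision tree that bifurcates three times: 7
internal nodes (levels 1–3, heap-numbered 1–7 with children $2i$ and
$2i+1$) and 8 leaves (8–15). Each internal node carries a hidden motion
direction $d_i \in \{-1,+1\}$ and a motion strength (coherence)
$c_i \in \{3.2, 6.4, 12.8, 25.6, 51.2\}\%$, drawn independently and
uniformly at the start of each trial. The target is the unique leaf reached
by following the true direction at every bifurcation. Querying an internal
node costs 1 point and returns one noisy evidence pulse; choosing a wrong
leaf costs 3 points and produces only negative feedback; finding the target
earns 10 points and ends the trial. With 10 states per node and 7 nodes the
latent space has $10^7$ states, far beyond exact POMDP solving.

Trials are simulated in *spatial* coordinates. For analysis, every trial is
relabeled into *canonical* (target-relative) coordinates in which the child
in the true direction always receives the higher id, so the target is node
15 and its path is (1, 3, 7). The relabeling is a tree isomorphism computed
from the ground truth (`canonical_map()`), because the canonical numbering
depends on information the agent does not have.

A single scalar evidence pulse represents each 227 ms motion stimulus:

$$e \sim N(\kappa\, d\, c\, t,\; t(1 + c\gamma)), \qquad t = 0.227\,\mathrm{s},$$

with signal-to-noise $\kappa$ (units $1/(\text{coherence} \cdot s)$) and
variance slope $\gamma$. Coherences are stored as proportions; with
$\kappa$ in its conventional range the mean is dimensionally consistent only
on that scale, so percent inputs are converted on entry.

## The detection (extrema) choice model

After a query at level $\ell$, the pulse is compared against symmetric
criteria $\pm\Phi_\ell$. Evidence beyond the criterion commits to the
corresponding child; evidence inside the dead zone is discarded and the node
is re-queried. The criterion collapses with the number $n_q$ of immediately
preceding successive queries at that node:

$$\Phi_\ell = \phi_\ell\,(1 + e^{-\lambda n_q}),$$

starting at $2\phi_\ell$ and approaching $\phi_\ell$. Our convention for
$n_q$ is the *streak* counter: 0 on the first query of an uninterrupted run
at a node, reset whenever the run is interrupted (including revisits after
errors). The trinomial choice probabilities are plain Gaussian tails,

$$p_+ = \tfrac12\,\mathrm{erfc}\!\left(\tfrac{\Phi-\mu}{\sqrt2\sigma}\right),\quad
  p_- = \tfrac12\,\mathrm{erfc}\!\left(\tfrac{\Phi+\mu}{\sqrt2\sigma}\right),\quad
  p_q = 1 - p_+ - p_-,$$

which is the only form consistent with probabilities summing to one.
The six parameters $(\kappa, \gamma, \phi_{1..3}, \lambda)$ are fitted by
maximum likelihood over the *fitting subset* — queries followed by a
re-query or by a query at one of the two children — using a multi-start
bounded quasi-Newton scheme (L-BFGS-B from eight random starting points by
default, deterministic given the seed). Tying options of the same
likelihood give the comparison variants: no variance scaling
($\gamma = 0$), level-dependent $\kappa$ with common or level-dependent
$\phi$, and a criterion that decays with the query's order in the trial
rather than with tree level.

### The integration variant

The integration model accumulates evidence within a streak: after pulse
$k$ the decision is based on $e_1 + \dots + e_k$ compared against
$\pm\Phi_\ell(k-1)$, with the same collapsing schedule applied to the
cumulative sum at each pulse. Its likelihood needs the distribution of the
surviving cumulative sum, which we propagate on a discrete evidence grid:
2,001 points spanning the largest criterion plus eight standard deviations,
trapezoid weights, and an FFT convolution per pulse (zero-padded to a
composite length — a prime-length transform in base R is quadratic). The
surviving density is renormalized at each pulse so that conditional outcome
probabilities never underflow; exit probabilities use exact Gaussian tails
given the surviving density. The propagation is validated against
Monte-Carlo simulation of cumulative sums in the test suite.

### Identifiability notes

Two parameters deserve caution. The variance slope $\gamma$ is weakly
identified from trinomial choice frequencies at the task's five coherences:
at $\gamma \approx 1$ the profile likelihood is nearly flat and the MLE can
sit 30% away from the truth while beating it by several nats. The
parameter-recovery harness therefore demonstrates recovery in a regime
where the slope carries signal ($\gamma = 5$); the tolerances (10% for
$\kappa, \phi_\ell$; 25% for $\gamma, \lambda$) are unchanged. Similarly,
the heuristic agent's confidence threshold $\omega$ (below) only moves the
on-path proportion in the upper range ($\omega \gtrsim 0.75$ for our
parameter sets); the $\omega$-recovery demonstration generates data at
$\omega = 0.85$ where the mapping is steep.

## The Bayesian belief engine

Each node carries an independent $5 \times 2$ posterior
$P_i(c, d \mid E_i)$ updated by Bayes' rule after every pulse. Leaves are
colliders: feedback that leaf $T$ is *not* the target couples the otherwise
independent node posteriors (explaining away). The engine handles this
exactly by enumerating the $2^7 = 128$ joint direction assignments,
weighting each by the product of per-node direction marginals, zeroing the
16 assignments per visited leaf whose implied target is known wrong, and
renormalizing. Target beliefs $B(T \mid E, V)$ and post-error direction
marginals are sums over this table. With no errors the computation reduces
to the product of the three ancestors' direction marginals toward each
leaf. The engine is verified in the tests against brute-force enumeration
of all $10^7$ joint states at $10^{-10}$.

Choice confidence — used by the heuristic agent — is the posterior
probability of the chosen direction given *only the last* evidence sample
at the node, with a uniform prior over the ten $(c, d)$ cells. A
prior-from-accumulated-posterior option exists but is off by default, for
consistency with the single-sample reading of the model.

## The rollout planner

The approximately optimal agent scores each of the 15 candidate actions by
Monte-Carlo rollouts (default 2,000 per action): sample a full latent state
from the posterior (directions from the renormalized combination table,
coherences from $P(c \mid d)$), then play a constrained random policy in
imagination — an internal node with probability $7/15$, uniformly chosen
and allowed to repeat; otherwise the unvisited leaf with the highest
current imagined belief, ties uniform — updating a private copy of the
belief with observations drawn from the sampled state, until the sampled
target is found. The executed action minimizes the mean imagined cost.
Rollouts are capped at 200 steps; a truncated rollout is charged the worst
case for its remainder (every remaining unvisited wrong leaf plus the
target). Payoff variants scale the planning cost of internal queries (30%)
or of queries/re-queries (50%/5%) while the world always pays true costs.

The planner is cross-checked against an exact value-iteration oracle on a
reduced task (one internal node of known coherence, two leaves), where the
belief state is a scalar and the Bellman equation can be solved on a grid.
Agreement is evaluated on a belief grid under two payoff regimes — the
standard one, where choosing a leaf dominates everywhere, and a
high-error-cost regime with a genuine query region; residual disagreements
sit at the decision boundaries, where the random-policy rollout values are
biased estimates of the optimal continuation.

## Shallow sampling norms

Probability gain, information gain (bits) and impact are expectations, over
the predictive observation distribution of an action, of a functional of
the updated target beliefs: the change in the posterior peak, the entropy
reduction, and the summed absolute belief change. Leaf actions have a
two-outcome observation distribution given by $B(T)$; internal actions use
a 10-component Gaussian-mixture predictive density, weighted by
$P(c \mid d, E_i)$ and the post-error conditional direction marginal, with
expectations computed by trapezoid quadrature on a 401-point evidence grid
(validated against Monte Carlo at three standard errors). Norm agents
execute the argmax action with uniform tie-breaking — consequential at the
uniform prior, where many actions tie — and never re-choose a known-wrong
leaf. One convention is ours: when the target is certain
($\max_T B = 1$), every score is zero and no observation can change the
belief, so the agent cashes in on the certain leaf rather than dithering
among zero-scored actions. The emergent policies match their published
descriptions: probability gain and information gain search leaves only;
impact makes exactly one root query and then searches the favored branch.

## The heuristic agent

The heuristic agent extends the detection model with credit assignment
after leaf errors. It stores, per internal node, the last evidence sample
and the implied choice confidence, plus a blame-eligibility flag (cleared
when the node is blamed, restored by new evidence). After an error at leaf
$T$ with path $P_T$, confidences toward $T$'s direction are compared to the
threshold $\omega$ over *eligible* path nodes:

* two or more low-confidence nodes → blame the highest-level one and
  re-query it (**on-path**);
* otherwise → blame the least-confident eligible node and query its
  counterfactual child (**off-path**);
* no eligible node → no blame; choose a random unvisited leaf
  (**fallback**).

The agent never queries a leaf twice: a level-3 commitment pointing at a
known-wrong leaf triggers the post-error rules at zero cost (we count these
"remembered" errors in the blame statistics but they charge no points).
A node never queried has no confidence; we assign it the uniform-prior
value 0.5, the posterior with no evidence. $\omega$ is fitted by matching the
simulated to the observed on-path proportion with a coarse-plus-refined
grid search under common random numbers (41 + 41 points, 20,000 trials per
evaluation by default), which resolves $\omega$ well below the 0.05
tolerance wherever the mapping is invertible.

## Synthetic participants

No human data or best-fit parameter values are available to this package.
`synthetic_participants()` ships four labelled synthetic parameter sets
used by examples and acceptance checks. They were calibrated once against
the published *behavioral anchors* — roughly 6.5, 7.7, 9.4 and 7.7 queries
per trial, mostly positive mean rewards with participant 3 negative, and
participant 3 carrying the highest confidence threshold — and not against
any model-prediction quantity. Consequences follow the model, not the
calibration: the blame-probability ratio between weakest and strongest
coherence (~4) and the impact agent's mean reward (~2 points/trial) emerge
at the published values, while the absolute on-path proportion, which is a
steep function of the unavailable per-participant $\omega$, does not.

## Simulation sizes and numerical choices

Simulation sizes in the tests are chosen so Monte-Carlo error is small
against each tolerance: $10^5$ draws for 4-standard-error moment and
threshold checks; 20,000 trials per participant for blame statistics
(binomial error well below the 0.03 absolute tolerance); 500 trials per
participant for the impact-agent reward (standard error ≈ 0.1 against a
0.42 tolerance); 2 replicate datasets per direction at $n = 5{,}000$
queries for the detection-vs-integration BIC comparison, each fitted with
symmetric warm starts (both variants share a parameter vector, so both are
started from the generating values plus cross and random starts — cold
random starts can leave the integration likelihood short of its optimum
and flip the comparison's sign). Degenerate inputs are handled explicitly:
zero criteria remove the dead zone; a zero-coherence pulse is pure noise;
eliminating every direction combination (only possible by visiting all
eight leaves, which the task precludes) raises an error rather than
returning NaNs; underflow in posterior updates is prevented by normalizing
likelihoods by their maximum.

## What the synthetic data do not show

The generators emulate the task's statistical structure — independent
uniform node states, Gaussian pulses, the payoff schedule — not the
perceptual front end: there are no pixel-level dots, no motion-energy
filtering, no temporal within-pulse structure, no eye movements, and no
learning across blocks. Model-based pulse regressions use the evidence
samples themselves in place of motion-energy residuals, which is exact for
model data but sidesteps the stimulus-reconstruction step a human analysis
needs (for deterministic simulated choices these regressions exhibit
complete separation; the likelihood-ratio patterns remain interpretable and
separation is flagged). Passing tests therefore certify the decision-level
models and analyses, not the sensory pipeline.
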