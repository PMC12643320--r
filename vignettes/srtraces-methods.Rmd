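---
title: "Models and methods behind srtraces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srtraces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtraces)
```

## The scientific question

In graph serial reaction time tasks, a participant responds for 1500
trials to cues generated by a random walk on a hidden 15-node, 4-regular
graph (modular, ring-lattice, or random). Reaction times shorten for
expected stimuli, and — remarkably — the expectancies that show through the
RTs span multiple future steps: they behave like a successor
representation (SR), the matrix of temporally discounted expected future
state occupancies

$$M = T + \gamma T^2 + \gamma^2 T^3 + \cdots = T(I - \gamma T)^{-1},$$

where $T$ is the one-step transition matrix and $\gamma \in [0,1)$ the
discount (a one-step-ahead convention: row $s$ aggregates occupancies from
the step after $s$). The question this package operationalizes is *how*
such long-run predictions are learned trial by trial: by chaining one-step
bootstrap backups (SR-TD(0)), by eligibility traces that broadcast each
observation to recently visited states (SR-TD(1), Monte-Carlo-like), or a
mixture, indexed by the trace parameter $\lambda$.

## Learners

All learners run over the full stimulus sequence, including trials later
excluded from the likelihood.

* **Recency** (`recency_init`/`recency_update`): an unconditional
  expectancy vector, $W \leftarrow (1-\alpha) W + \alpha\, I(s_t)$,
  initialized uniform. Its predictor for trial $t$ is $W[s_t]$ *before*
  the trial-$t$ update — the model's guess about the upcoming node.
* **One-step** (`onestep_update`): a conditional transition estimate;
  the predecessor's row decays by $(1-\alpha)$ and the observed entry
  gains $\alpha$, so rows remain exactly stochastic.
* **SR-TD($\lambda$)** (`sr_td_update`): dutch-trace temporal-difference
  learning of $M$, per transition in this order: trace increment
  $e[s_{t-1}] \leftarrow (1-\alpha)e[s_{t-1}] + 1$; TD error
  $\delta = I(s_t) + \gamma M[s_t,\cdot] - M[s_{t-1},\cdot]$; broadcast
  $M[s',\cdot] \mathrel{+}= \alpha\, e[s']\, \delta$ for every state;
  decay $e \leftarrow \gamma\lambda e$. The literal increment-first order
  means the current transition is itself trace-weighted. $M$ starts at
  the SR of the uniform kernel, $(I-\gamma T_u)^{-1} T_u$, and is never
  renormalized during learning; normalization happens only in the readout
  $M[s_{t-1}, s_t] / \sum_j M[s_{t-1}, j]$.
* **Static SR** (`static_sr`): $\hat T(I-\gamma\hat T)^{-1}$ from the
  empirical transition matrix of the entire walk — the no-learning
  reference.
* **Trace-only Hebbian** (`hebbian_trace_update`): a bootstrap-free
  $\lambda = 1$ reference. When a state's trace is refreshed its own row
  forgets by $\alpha u$ ($u$ the fresh dutch increment), every eligible
  state's row gains $\alpha e[s']$ at the observed column, and
  $e \leftarrow \gamma e$. This specific variant is *derived from* the
  $\lambda = 1$ telescoping identity (below); other trace-only variants
  with different transients exist, and this one is used for cancellation
  checks and signature simulations, never for subject fitting.

**Why $\lambda = 1$ needs no bootstrap.** Accumulate the trace-weighted
bootstrap components $e_t \otimes (\gamma M[s_t,\cdot] -
M[s_{t-1},\cdot])$ along a walk with $\lambda = 1$ against a frozen $M$:
because the trace decays by exactly $\gamma$, each $+\gamma M[s_t,\cdot]$
term is canceled by the next trial's $-M[s_t,\cdot]$ term, except for
(i) a local forgetting term at each visited state (implementable with a
scalar eligibility, no error vector) and (ii) a single trailing boundary
term $\alpha\, e_{\mathrm{end}} \otimes M[s_T,\cdot]$. The acceptance
suite verifies this identity to machine precision and checks that live
SR-TD(1) and Hebbian learners stay within $\alpha \max|M|$ of each other.

## Observation model

RTs follow a shifted log-normal, $\log(rt_t - \text{shift}) \sim
\mathcal N(\mu_t, \sigma^2)$, with

$$\mu_t = \mu_0 + \beta_{trial}\, t + \text{target}_{2\ldots15} +
\beta_A A_t + \beta_W W_t + \beta_{ntrials}\, r_{ntrials} +
\beta_{lag10}\, r_{lag10},$$

where $A_t$ is the higher-order predictor (one-step, SR-TD, or static
SR), $W_t$ the recency predictor (combined models), and the nuisance
regressors are the trials since the current node last occurred and
$\log(1 + \text{count of the node in the last 10 trials})$. Choices worth
recording:

* The trial index is rescaled to $[0,1]$ within each stage; learner state
  restarts fresh each stage (stages use different graphs/walks).
* The shift is a fitted fraction (logit-transformed) of the session's
  minimum *included* RT, so the likelihood support always covers the
  data.
* Motor-target category 1 is absorbed into $\mu_0$; categories 2–15 get
  offsets.
* The recency-model equation indexes $W$ by the upcoming node; a
  two-index form appearing in the combined-model equation is treated as
  the same vector readout $W[s_t]$ (the vector has no second index).
* Nuisance regressors are z-scored within session (configurable off) so
  their weights are comparable across subjects.
* For a never-before-seen node, `r_ntrials` is the trial index and the
  trial is flagged; `r_lag10` uses $\log(1+\text{count})$ so the frequent
  zero counts stay finite. Both conventions only matter inside the
  equilibration window, which carries no likelihood.
* Incorrect trials and RTs under 30 ms are excluded from the likelihood
  but still advance the learners; the first 500 trials of each stage
  equilibrate the learners and carry no likelihood either.

## Hierarchical estimation

Per-session parameters $\theta$ live on an unconstrained scale (logit for
rates, discount, trace and shift fraction; log for $\sigma$; identity
elsewhere) with an identity-covariance Gaussian prior centered at
$m + c\,\Delta$, where $c = \mp 1$ codes first/second stage. The MAP
objective is `sequence_nll(theta) + 0.5 * ||theta - (m + c D)||^2`.

Because $\mu_t$ is linear in everything except the learner rates and the
shift, the linear coefficients have a closed-form ridge solution and
$\log\sigma$ a one-dimensional Newton solution; the optimizer therefore
searches only the 1–5 nonlinear coordinates (multi-start Nelder-Mead,
jittered starts from a derived seed, relative tolerance `1e-9`). A
parameter point whose learner diverges (any $|M| > 10^3$, possible for
large $\alpha\gamma\lambda$) returns an infinite objective and is
rejected.

EM alternates these MAP fits with a group-level regression of the MAP
vectors on $[1, c]$ (mean plus stage coefficients; the covariance stays
the identity by design), stopping when the largest group-mean change
drops below `1e-3` or at the iteration cap. Because the prior covariance
is never updated, only MAPs are needed during iterations; Laplace
Hessians (central finite differences, step `1e-3`) are computed at the
final iterate. A final multi-start polish pass is always run: the
nonlinear coordinates have local optima and warm single-start fits can
stick. The Laplace marginal likelihood is
$-\log p(\text{data}) \approx \text{negLogPost}(\hat\theta) -
\tfrac{d}{2}\log 2\pi + \tfrac12 \log\det H$ (with the prior's
normalizing constant inside negLogPost; verified against the exact
conjugate-Gaussian marginal in the tests). Model scores add an AIC
penalty of one NLL unit per group-level parameter, divided equally
between sessions — the per-parameter unit is a convention (scores are
NLLs), exposed as an argument. Comparisons are one-sided paired t-tests
on per-session scores, dropping non-converged sessions pairwise.

## Model-agnostic signatures

The trace signature compares final-element RTs of `S,X,T,S,T` windows
(trace learners have boosted $S\to T$ via the initial `S,X,T`) against
recency-matched `X1,X2,T,S,T` controls; the bootstrap signature compares
`B,T,S,B,S,T` against `X,T,S,B,S,T`. Matching conventions: overlapping
windows all count; `X1` may equal `X2` (only the recency of `S` must be
broken); a window matching the test template is never also a control
(the templates are exclusive on the first element); matches are found on
the raw sequence, and a match is dropped only if its final RT was
excluded. Contrasts are mixed-effects fits on untransformed millisecond
RTs with random intercepts and slopes by subject and graph instance,
falling back to random intercepts when the slopes fit is singular, and
dropping a grouping factor entirely when it has a single level (as in
single-condition simulations).

The novel-cluster analysis residualizes log RTs with the baseline model
(trial and motor terms only), locates first and second entries into a new
cluster (a second entry requires staying in the new cluster), and fits
`resid ~ time_since_node + cluster_step + (1 + cluster_step | subject)`
with the recency lag capped at 100 trials and effects-coded as a
categorical control. A negative `cluster_step` effect — second entry
faster — is the SR's prediction and not the recency learner's.

## The synthetic cohort generator

The generator mirrors the task: 15-node 4-regular graphs, 1500-trial
random-walk stages, one or two counterbalanced stages per subject, a
seeded random bijection of nodes onto motor categories, RTs sampled from
the shifted log-normal at the agent's $\mu_t$. Contamination is minimal
by design: fast guesses are uniform on (1, 30) ms and marked correct
(default rate 0.5%), errors keep their sampled RT and are marked
incorrect (default 3%) — enough to exercise the preprocessing rules
without modeling error mechanisms. Default agent parameters are one-time
choices of plausible magnitudes: $\mu_0 = 5.7$ ($\approx 300$ ms over a
200 ms floor), $\sigma = 0.25$ (a ~25% RT coefficient of variation),
$\beta_{trial} = -0.1$ (modest practice effect), facilitatory
$\beta_A = -1.0$ and $\beta_W = -0.6$, $\alpha_A = 0.1$,
$\alpha_W = 0.2$, $\gamma = 0.8$ and $\lambda = 0.75$ (inside the ranges
estimated for such tasks), with between-subject SDs of 0.5 on the
logit-scale learner parameters and 0.1–0.3 on the location terms. What
the generator deliberately does *not* emulate: residual RT
autocorrelation, fatigue beyond the trial slope, lapses, or any
systematic error process — so passing recovery tests demonstrate
estimator correctness under the model's own assumptions, not robustness
to real-data misspecification.

## Problem sizes, numerical choices, and honest limits

Test and acceptance runs use desk-scale studies: cohorts of 8–40
subjects with single 1500-trial stages, EM capped at a few iterations
after which group means are stable to ~0.1 on the unconstrained scale,
and 10-replicate designs for recovery claims. Convergence of SR-TD to
the analytic SR is scored on the *window-averaged* $M$ over the final
10^4 steps of a 2×10^5-step walk at $\alpha = 0.02$: a constant step
size never stops fluctuating (per-step max-abs deviations are ~0.1), so
the time average is the natural estimator of the converged
representation; even it retains ~0.03–0.08 of autocorrelated noise on
the modular graph, whose cluster structure mixes slowly.

Two estimation limits are worth stating plainly, and the recovery
quantities the acceptance script reports measure them directly. First,
with 1000 likelihood-bearing trials per subject the per-subject
likelihood localizes $\lambda$ only weakly (profiling it with all other
parameters held at truth leaves a logit-scale SE above 1), so
subject-level truth-estimate correlations for $\lambda$ — and to a
lesser degree $\gamma$ and $\alpha_A$ — are capped well below what the
$\beta$ weights achieve, even though group-level means recover well.
Second, distinguishing an interior $\lambda$ from $\lambda$ fixed at 1
by paired score tests carries per-subject effects of a fraction of an
NLL unit; at cohort sizes an order of magnitude below a full study the
test is underpowered, and its replicate pass rate in the acceptance
suite should be read with that in mind. Both are properties of the
inference problem at these data sizes, not of the implementation —
the oracle-equivalence, cancellation, surprisal and signature checks,
which are not information-limited, are the sharp tests of correctness.
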