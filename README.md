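# srtraces

Trial-by-trial successor-representation learning from reaction times.

## The problem

In graph serial reaction time tasks, people respond to a stream of cues
generated by a random walk on a hidden 15-node graph. Their reaction
times betray learned expectancies that span multiple future steps — the
profile of a **successor representation (SR)**,

    M = T + γT² + γ²T³ + … = T(I − γT)⁻¹,

the discounted expected future occupancy of each node given the current
one. How is such a long-run prediction learned trial by trial? The
candidate mechanisms are one-step **bootstrapping** (SR-TD(0)), decaying
**eligibility traces** (SR-TD(1), Monte-Carlo-like), or any mixture —
the SR-TD(λ) family with dutch traces. `srtraces` is a toolbox for
researchers in computational cognitive science to pose that question to
RT data and to synthetic cohorts:

* 4-regular stimulus graphs (modular / ring-lattice / random) and
  random-walk sequence generators;
* trial-by-trial learners (recency, one-step transition, SR-TD(λ),
  static SR, trace-only Hebbian) plus closed-form SR oracles;
* a shifted log-normal RT likelihood,
  `log(rt − shift) ~ N(μ_t, σ²)`, with trial, motor-target and recency
  nuisance terms;
* hierarchical EM fitting (identity-covariance Gaussian prior on an
  unconstrained scale, Laplace-approximated marginal likelihoods,
  AIC-penalized paired model comparisons);
* model-agnostic sequence signatures of trace (`S,X,T,S,T` vs
  `X1,X2,T,S,T`) and bootstrap (`B,T,S,B,S,T` vs `X,T,S,B,S,T`)
  updating, and the first- vs second-cluster-entry analysis;
* a synthetic-cohort generator with truth records for parameter- and
  model-recovery studies.

## A worked example

Simulate a small cohort of combined SR-TD(λ) + recency agents, fit two
models hierarchically, and compare them:

```r
library(srtraces)

sim <- simulate_cohort(cohort_spec(n_subjects = 10, n_trials = 1500,
                                   seed = 42))
cfg <- fit_config(max_em_iter = 3)

fit_rec <- em_fit("recency", sim$trials, config = cfg, seed = 1)
fit_sr  <- em_fit("combined_sr_td", sim$trials, config = cfg, seed = 1)
fit_sr

cmp <- compare_models(model_score(fit_rec), model_score(fit_sr))
round(unlist(cmp[c("t", "p", "mean_diff")]), 4)
```

```
<sr_em_fit> combined_sr_td: 10 sessions, 3 EM iterations (max iterations)
  group means (natural scale):
       mu0      sigma     beta_A     beta_W    alpha_A    alpha_W      gamma 
    5.6801     0.2520    -1.0051    -0.6007     0.0850     0.1965     0.7595 
       lam shift_frac 
    0.6134     0.7017 
        t         p mean_diff 
   1.9937    0.0387    4.8087 
```

The cohort was generated at group means `beta_A = -1.0`, `beta_W = -0.6`,
`alpha_A = 0.1`, `alpha_W = 0.2`, `gamma = 0.8`, `lam = 0.75`, and the
estimates land close (β weights negative: predicted nodes are answered
faster; γ ≈ 0.76 corresponds to a temporal horizon `1/(1−γ)` of about 4
steps; λ well above 0 means learning leans on eligibility traces more
than bootstrapping). The paired comparison says the combined model
improves on recency alone by ~4.8 penalized-NLML units per session
(one-sided p ≈ 0.04 at this toy cohort size).

The signature analyses work directly on trial tables:

```r
matches <- find_patterns(sim$trials, "trace")
signature_contrast(matches, "trace")
```

```
<contrast> trace: effect -7.14 (SE 3.43), z = -2.09, p = 0.0371, n = 1993 [random intercepts only]
```

The negative `is_test` effect means the final response of `S,X,T,S,T`
windows is ~7 ms faster than in recency-matched `X1,X2,T,S,T` controls —
the fingerprint of trace updating (these agents were simulated with
λ = 0.75).

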