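---
title: "Modelling informative missing binary outcomes in network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling informative missing binary outcomes in network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misnma)
```

## The problem

Randomised trials of a binary outcome routinely lose participants before the
outcome can be ascertained. Analysing completers only is an implicit
missing-at-random (MAR) assumption; when dropout is related to the unobserved
outcome — participants leaving *because* they improved, or because they did
not — the completer analysis is biased and, just as importantly, overstates
its own precision. In a network meta-analysis (NMA), where several
interventions are compared jointly through direct and indirect evidence, the
problem compounds: different interventions can carry different amounts of,
and reasons for, missingness.

`misnma` fits Bayesian random-effects NMA models for arm-level binary data
in which the missing counts are part of the likelihood, linked to the
outcome through the **informative missingness odds ratio** (IMOR), and the
analyst's beliefs about the missingness mechanism enter as a prior on the
log IMOR.

## The core model

For arm $k$ of trial $i$, with $n_{i,k}$ randomised, $m_{i,k}$ missing and
$r^o_{i,k}$ events among the $n^o_{i,k} = n_{i,k} - m_{i,k}$ completers, the
underlying event risk $p_{i,k}$ follows the usual logistic NMA structure

$$\operatorname{logit}(p_{i,k}) = u_i + \theta_{i,k},$$

with $u_i$ the baseline-arm log odds, $\theta_{i,k}$ the trial-specific log
odds ratio against the baseline arm, and
$\theta_{i,k} \sim N(\mu_{t_{i,k}A} - \mu_{t_{i,1}A},\ \tau^2)$ under
consistency. Multi-arm trials use the equivalent sequential conditional
normals (variance $(k/(2(k-1)))\tau^2$ for the $k$-th arm position), which
reproduce the joint multivariate normal with covariance $\tau^2/2$.
Functional parameters $\mu_{tl} = \mu_{tA} - \mu_{lA}$ are always derived
draw-by-draw, never sampled.

Missingness enters in one of two factorizations of the same joint
distribution of outcome and missingness indicator:

* **Pattern-mixture (PM)**: $m_{i,k} \sim \text{Bin}(q_{i,k}, n_{i,k})$ and
  $r^o_{i,k} \sim \text{Bin}(p^o_{i,k}, n^o_{i,k})$, where the completer
  risk $p^o$ solves the mixture identity
  $p = p^o (1-q) + p^m q$ with
  $\operatorname{logit}(p^m) = \operatorname{logit}(p^o) + \varphi$.
  `pm_observed_risk()` evaluates this as the root of a quadratic in a
  cancellation-free closed form.
* **Selection**: one multinomial over (observed event, observed non-event,
  missing) with cells built from the conditional missingness probabilities
  $c_1$ (among events) and $c_0$ (among non-events), where
  $q = c_1 p + c_0 (1-p)$ and
  $\operatorname{logit}(c_1) - \operatorname{logit}(c_0) = \varphi$
  (`selection_cells()`).

Both $\varphi$'s equal the log joint odds ratio of the 2×2
event-by-missingness table, so the two factorizations imply the same cell
probabilities; algebra shows their full log-likelihoods are *exactly* equal,
combinatorial constants included. The test suite checks both facts
numerically, which is the computational face of the observation that PM and
selection analyses give near-identical NMA estimates.

## Prior structures for the log IMOR

$\varphi = 0$ is MAR; $\varphi \sim N(0, \sigma^2)$ with $\sigma^2 = 1$
encodes "MAR on average" with realistic uncertainty ($\sigma^2 \in
[0.25, 4]$ spans liberal to conservative choices and is exposed as
configuration). Six structures shape how the $\varphi_{i,k}$ relate:

| structure | scope | parameters |
|---|---|---|
| identical | intervention | one $\varphi$ per intervention |
| identical | trial | one $\varphi$ per trial |
| identical | network | a single $\varphi$ |
| hierarchical | intervention | latent $\varphi_{i,k}$, $(\mu^\varphi, \sigma)$ per intervention |
| hierarchical | trial | latent $\varphi_{i,k}$, $(\mu^\varphi, \sigma)$ per trial |
| hierarchical | network | latent $\varphi_{i,k}$, one $(\mu^\varphi, \sigma)$ |

Hierarchical group means get $N(0, 1)$ priors and group SDs $U(0, 1)$;
both hyper-choices are configurable in `imor_prior()`. The remaining priors
follow standard vague NMA practice: $N(0, 10^4)$ on $u_i$ and $\mu_{tA}$,
half-normal $HN(0, 1)$ on $\tau$. (A quoted median of 0.98 and IQR
0.51–1.96 sometimes attached to this prior actually matches a standard
log-normal; the half-normal's median is 0.674. We implement the half-normal
with a configurable scale.) Each arm's missingness probability $q_{i,k}$
gets a flat Beta(1, 1) prior.

## Sampling

`fit()` runs an adaptive random-walk Metropolis-within-Gibbs sampler
written for this model family:

* trial baselines $u_i$ and contrasts $\theta$ update in parallel across
  trials (their full conditionals factor by trial);
* each basic parameter additionally gets a *joint shift* move that
  translates $\mu_{tA}$ together with every contrast whose random-effects
  mean involves it — the shift leaves the random-effects density invariant,
  so the proposal is informed directly by the likelihood. This decouples
  the centred parameterisation and raises the effective sample size of the
  basic parameters several-fold;
* $\tau$ is sampled on the log scale (half-normal density plus Jacobian),
  which avoids sticking at the $\tau \to 0$ boundary;
* per-arm $q$ and the $\varphi$ blocks update in parallel over disjoint
  groups; hierarchical group means use exact normal-normal Gibbs draws and
  group SDs a logit-bounded random walk;
* proposal scales adapt towards roughly 20–40% acceptance in batches of 50
  during burn-in and are frozen afterwards.

Initial values are data-driven (empirical completer logits, contrasts at 0,
$\tau$ at its prior median, $\varphi$ at its prior mean) with up to 100
jittered restarts if the joint density is not finite. Convergence is
reported per parameter via the Gelman–Rubin statistic and a simple
autocorrelation-based effective sample size; `fit()` warns — never errors —
when any $\hat R$ exceeds the threshold (default 1.05).

The sampler is validated against an independent oracle: on a single two-arm
trial without missingness, dense 400×400 two-dimensional quadrature of the
exact posterior, with agreement required to 0.01 on the posterior mean and
5% on the posterior SD.

## Node-splitting and ranking

`node_split()` fits one joint model in which trials containing both members
of the split comparison inform an isolated direct-effect parameter, the
rest of the network supplies the indirect effect through the consistency
structure, and a single $\tau^2$ is shared. The inconsistency factor is
IF = direct − indirect per draw. Because no convention fixes the sidedness
of the reported conflict probability, we report the two-sided
$2\min\{P(\text{IF}>0), P(\text{IF}<0)\}$ *and* both one-sided tails.
Multi-arm trials containing the split pair are assigned to the direct
component with their remaining contrasts dropped; this is a documented
package choice for a case with no established rule (the simulation design
uses two-arm trials only, so nothing downstream depends on it).

`rank_probabilities()` orders the basic parameters in every draw; ties are
broken by a uniform random permutation, making the rank table exactly
doubly stochastic.

## The simulator

`sim_scenario()` encodes a triangle network of two-arm trials — new (N) and
old (O) interventions and placebo (P), with a typical loop of 1 NO, 3 NP
and 4 OP trials — and `simulate_network()` generates observed datasets:

1. Arm sizes per trial from U(102, 187) (placebo-controlled) or U(128, 241)
   (old-controlled); control-arm initial risks from U(0.27, 0.40) and
   U(0.63, 0.76).
2. True effects $\mu_{NP} = \log 2$, $\mu_{OP} = \log 1.5$, and
   $\mu_{NO} = \mu_{NP} - \mu_{OP} + IF$ with the inconsistency factor
   drawn from a scaled-shifted $t_3$ (scale 0.44) centred at 0 (low) or 1
   (moderate).
3. One heterogeneity draw per network from the predictive log-normals
   LN(−3.95, 1.34²) (small, median ≈ 0.02) or LN(−2.56, 1.74²)
   (substantial, median ≈ 0.08).
4. A shared trial deviation $\varepsilon_i \sim N(0, \tau^2)$ split between
   arms with weights $(a, 1-a)$ summing to one, so the *contrast* variance
   is exactly $\tau^2$ for any split. The exact split in the original
   two-stage generation scheme is not public; we encode the qualitative
   constraint that placebo log odds vary less by default ($a = 0.25$ for
   placebo arms, $0.5$ in old-controlled trials), and expose $a$ as
   `placebo_var_fraction`.
5. Missingness probabilities per the extent/balance rules (moderate
   U(0.05, 0.20), large U(0.21, 0.40); unbalanced scenarios give control
   arms the higher range), and log IMORs per arm: under the informative
   mechanism, active arms draw from $N(\log 2, 1)$ truncated below at 0 and
   placebo from $N(-\log 2, 1)$ truncated above at 0 — the direction
   consistent with active-arm participants being twice as likely to go
   missing because their outcome improved; under MAR, $N(0, 1)$.
6. Observed counts by the exact joint law of the 2×2 table: among the
   complete-data events a $\text{Bin}(c_1, \cdot)$ number goes missing,
   among non-events $\text{Bin}(c_0, \cdot)$, with $(c_1, c_0)$ from
   `selection_cells()`. This participant-level coupling is
   distribution-identical to drawing $m \sim \text{Bin}(q, n)$ followed by
   $r^o \sim \text{Bin}(p^o, n - m)$, and has the additional property that
   forcing $q = 0$ returns the complete data bit-exactly.

`true_prob_best()` computes the design's true ranking probabilities by
Monte Carlo, drawing $\theta_{NP} \sim N(\log 2, \tau^2)$ and
$\theta_{OP} \sim N(\log 1.5, \tau^2)$ with placebo at 0. We fix $\tau^2$
at the predictive median (0.02 or 0.08): this is the only reading we found
that reproduces all four published design probabilities (93%/7.3% and
76%/24% for new/old under small/substantial heterogeneity); mixing $\tau^2$
over the full predictive distribution does not, and remains available via
the `tau2` argument.

`run_study()` chains the generator, the model grid (`model_grid()` expands
the twelve missingness-model × prior-structure combinations) and optional
node-splitting of the N–O comparison into one long results table, with
per-replicate and per-fit seeds derived deterministically from a master
seed.

### What the generator does and does not emulate

The simulator reproduces the study conditions above: frequent events,
moderate-to-large trials, a single triangle loop, two-arm trials, and
missingness acting through intervention-specific log IMORs. It does not
emulate rare events, multi-arm trials, larger network topologies,
covariate-driven dropout, or reporting biases. Tests that pass on simulated
networks therefore demonstrate internal validity of the machinery under
these conditions, not robustness of the models on arbitrary real data.

## Problem sizes used by the test suite

The full-scale study design calls for 1000 replicates per scenario with
20 000 updates, burn-in 2000 and thinning 3 — the defaults `run_study()`
and `mcmc_options()` accept. The packaged checks use scaled-down versions
chosen to keep the full suite comfortably runnable on a laptop: 20
replicates with 2 chains × 5000 kept draws for the MAR-recovery check, 20
replicates × 2 models at 2 chains × 3000 kept draws for the
precision-ordering check, and 2 × 45 000 kept draws for the quadrature
oracle. These sizes are the package's own defaults for its checks; the
underlying functions accept the full-size settings unchanged.

## Numerical choices

* Quadratic roots for $p^o$ and $c_0$ are evaluated as
  $2c/(b + \sqrt{b^2 + 4ac})$, which is exact at $\varphi = 0$ (where the
  quadratic degenerates to linear) and stable for extreme $\varphi$;
  discriminants within $10^{-12}$ of zero are clamped to zero.
* Degenerate risks are $\varepsilon$-clamped at $10^{-12}$ inside
  likelihood evaluation only — user-facing transforms raise domain errors
  instead.
* Zero cells need no continuity correction: the binomial/multinomial
  likelihoods handle them natively.
* The Gelman–Rubin statistic returns 1 with a warning when all chains are
  constant (a parameter pinned by the data or the model), and `Inf` when
  chains are constant at different values.

## Known limitations

* The random-walk sampler is tuned for the small networks of the simulation
  design; very large networks would benefit from gradient-based samplers.
* The identical common-within-network structure is the slowest-mixing
  variant (a single $\varphi$ is pushed through every arm's likelihood);
  inspect its $\hat R$ before trusting it; this variant is known to be the
  most convergence-prone in practice.
* Contrast-level (log OR + SE) input, continuous outcomes and
  individual-participant data are out of scope; so are
  design-by-treatment-interaction inconsistency models and model-choice
  statistics such as DIC.
* The baseline arm of a multi-arm trial is, by convention, the first listed
  arm; no convention is universal, so `nma_network()` accepts a per-trial
  override.
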