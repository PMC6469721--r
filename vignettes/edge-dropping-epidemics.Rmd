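---
title: "SIR epidemics with preventive edge dropping: models, limits, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SIR epidemics with preventive edge dropping: models, limits, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgedrop)
```

## The model and its assumptions

`edgedrop` implements a Markovian SIR epidemic on a configuration-model
network in which susceptible individuals practise a simple form of social
distancing: they drop their edge to an infectious neighbour at a constant
rate. The ingredients are:

* a degree distribution $D$ with pmf $p_k$, mean $\mu_D$ and variance
  $\sigma^2_D$, from which the network is built by attaching $D_i$ stubs to
  individual $i$ and pairing stubs uniformly at random (self-loops and
  multi-edges are kept; one left-over stub is ignored when the total is
  odd). The *MR* version prescribes the degree counts deterministically;
  the *NSW* version draws them iid;
* per-edge infection at rate $\beta$, recovery at rate $\gamma$
  (exponential infectious periods), and per-edge dropping at rate $\omega$.
  Dropping is probabilistically equivalent to the infective *warning* each
  neighbour independently at rate $\omega$, with warned susceptibles cutting
  the edge — the formulation the simulator uses, since it lets the network
  be revealed edge by edge.

All asymptotic results assume a bounded maximum degree, which is why the
package works with explicitly truncated degree laws throughout.

The basic reproduction number is
$R_0 = \frac{\beta}{\beta+\gamma+\omega}(\mu_D + \sigma^2_D/\mu_D - 1)$:
the per-edge transmission probability times the mean number of onward stubs
of a size-biased neighbour. A recurring theme is the companion model with
recovery rate $\gamma+\omega$ and *no* dropping: it shares $R_0$, the
Malthusian parameter, the deterministic susceptible trajectory and the
final size with the dropping model, but not its stochastic properties —
dropping warns each neighbour independently, which *reduces* the
variability of the offspring counts and therefore raises the outbreak
probability and lowers the final-size variance.

## The effective-degree chain and its limits

The simulator and all limit theory run on the *effective-degree* state:
$X_i$ (susceptibles with $i$ unpaired stubs), $Y_i$ (infectives with $i$
unpaired stubs) and $Z_E$ (unpaired stubs on recovered individuals). An
infective stub activates at rate $\beta+\omega$; the activated stub pairs
with a uniformly chosen other stub; the event is a transmission with
probability $\beta/(\beta+\omega)$, otherwise a warning. Self-pairings
(an infective pairing two of its own stubs) are included in the simulator
and in the exact enumerator; in the drift and diffusion functions of the
fluctuation theory they are $O(1/N)$ and excluded.

Scaled by $N$, the chain is a density-dependent population process, so:

* the state fractions converge to the solution of an ODE system (the LLN
  limit), implemented in `solve_real_time()`;
* the fluctuations around that limit are asymptotically Gaussian with
  covariance solving
  $\dot\Sigma = G(w) + \partial F(w)\,\Sigma + \Sigma\,\partial F(w)^\top$,
  implemented in `solve_covariance()`. The drift $F$, diffusion $G$ and
  Jacobian $\partial F$ come from the enumerated jump list
  (`jump_model()`), and the closed-form drift is cross-checked against the
  jump sum at $10^{-12}$ in the tests, which guards every intensity
  transcription at once.

On an NSW graph the initial state is itself random (iid degrees); the CLT
then starts from the multinomial covariance `nsw_initial_covariance()`, and
the solution is the MR solution plus the homogeneously propagated initial
covariance — an additivity the tests verify directly.

### Transformed time and the final outcome

Running the clock at rate $\eta_E/y_E$ (stub prevalence in the
denominator) makes the susceptible block autonomous and gives closed
forms: the total stub fraction decays exactly like
$\mu_D e^{-2(\beta+\omega)t}$, and the susceptible block is a binomial
thinning of the initial degrees with escape probability
$\psi(t) = p_\omega + (1-p_\omega)e^{-(\beta+\omega)t}$,
$p_\omega = \omega/(\beta+\omega)$ (`closed_form_tilde()`). The infective
stub fraction hits zero at a finite time $\tilde\tau$ with
$z = e^{-(\beta+\omega)\tilde\tau}$ solving the final-size equation; the
real-time and transformed pictures are linked by the integrated-prevalence
time change $\xi(t)$, and $\theta(t) = \psi(\xi(t))$ recovers the familiar
edge-based variable (`solve_xi_theta()`). The identity
$\theta(t)=\psi(\xi(t))$ holds to $10^{-7}$ along solved trajectories and
is one of the package's standing consistency checks.

The final-size CLT needs the covariance at the *hitting time* of
$y_E = 0$, not at a fixed time. `hitting_projection()` applies the oblique
projector $B = I - (F \otimes \nabla\varphi)/(\nabla\varphi\cdot F)$,
$\varphi = y_E$, which removes the fluctuation in the crossing coordinate.
Because the transformed ODE is singular exactly at the hitting time, the
numerical route (`sigma2_mr_ode()`) stops at small positive levels
$\delta \in \{0.05, 0.02, 0.01\}$ and extrapolates $\delta \to 0$ with a
quadratic fit; it agrees with the analytic variance below to within 1% and
serves as its independent check.

### Analytic variances

`sigma2_mr()` evaluates the near-explicit MR variance: four closed-form
terms plus four 1-d quadratures over $v \in [z, 1]$ with smooth integrands
(adaptive quadrature, relative tolerance $10^{-11}$; $v = 0$ is never
reached since $z > 0$). `sigma2_0()` adds the fully explicit
degree-randomness contribution for NSW graphs. Two specializations are
fully explicit and are used as cross-checks of the general route rather
than shortcuts past it: for $\omega = 0$ the quadratures collapse (the
substitution $u = z^2/v$ turns them into antiderivatives of the PGF at $z$
and $z^2$), giving the classical network-SIR variances in
`sigma2_nodropping()`; for $\gamma = \omega = 0$ one obtains the
giant-component variances in `giant_component_variance()`, which the test
suite also confirms against the empirical sd of the largest component over
simulated NSW graphs.

All variance formulas require $z > 0$, i.e. a finite transformed extinction
time; $z = 0$ happens only in the degenerate case
$\gamma = \omega = 0$ with no degree-1 susceptibles, and the functions
refuse it explicitly rather than returning nonsense.

## Branching approximation

Early on, infection chains are nearly independent: an infective with $k$
susceptible neighbours infects
$Y_k \sim \mathrm{MixBin}\bigl(k, \tfrac{\beta}{\beta+\omega}(1 -
e^{-(\beta+\omega)I})\bigr)$, $I \sim \mathrm{Exp}(\gamma)$, of them.
`offspring_pgf()` uses the exact reduction to the positive finite sum
$\sum_m \binom{k}{m} a^m (1-a)^{k-m}\,\gamma/(\gamma + (\beta+\omega)m)$ —
stable at $k = 50$, where the alternating-series expansion would lose all
precision — and `offspring_pmf()` integrates the conditional binomial
against the density of $e^{-(\beta+\omega)I}$, again with a positive
integrand. Non-initial infectives have the size-biased-minus-one number of
susceptible neighbours; `p_major()` finds the extinction fixed point by
bracketed root-finding on $[0, 1 - 10^{-12}]$ (excluding the trivial root
at 1, as in the final-size solver) and reports
$1 - q^{n_\mathrm{initial}}$ for independent introductions.

## Numerical choices

* **PGF evaluation.** Two routes coexist deliberately. The ODE systems are
  finite, so everything tied to them (`closed_form_tilde()`,
  `solve_xi_theta()`, the consistency tests) evaluates PGFs by summing the
  truncated pmf (`pgf_method = "pmf"`): closed form and ODE then describe
  literally the same finite system and can be compared at $10^{-6}$.
  The asymptotic final-size and variance formulas default to the analytic
  untruncated PGFs of the named families (`pgf_method = "auto"`), the
  natural evaluation for quantities that do not live on the truncated
  state space. At the truncation points used here the two routes differ by
  less than the last printed digit of any reported quantity.
* **Truncation** renormalizes the pmf, so every probability invariant holds
  exactly; a warning fires when the discarded tail exceeds `tail_tol`.
  Defaults follow the study settings: Poisson(5) truncated at 15,
  Geometric(1/6) at 50; when no point is given the smallest point with
  tail mass below $10^{-8}$ is chosen.
* **Root-finding.** The final-size equation always has the trivial root
  $s = 1$ in the trace-of-infection regime; the solver brackets away from
  it, then polishes with Newton steps against the analytic derivative to a
  residual below $10^{-12}$. Downstream variance formulas consume this
  same root, never a re-solved one.
* **ODE solving.** `deSolve::lsoda` with rtol $10^{-8}$/atol $10^{-10}$
  for states; the covariance ODE integrates the lower triangle only (rtol
  $10^{-7}$). Transformed-time integrations stop at $y_E = \delta$ by root
  detection on the dense output rather than integrating through the
  singularity.
* **RNG.** All simulation code consumes R's RNG stream (the C++ cores call
  `unif_rand`/`exp_rand`), so one `set.seed()` makes an entire ensemble,
  and the CLI and acceptance script, byte-reproducible.
* **Exact enumeration.** `exact_final_size_pmf()` exploits that every
  transition strictly decreases (total stubs, number of infectives)
  lexicographically: the state graph is acyclic and absorption
  probabilities follow from one forward sweep, with no linear solve. It is
  the ground truth for the simulator on configurations with at most 10
  stubs.

## What the scenarios emulate — and what they do not

The built-in scenarios reproduce the study conditions: Poisson(5) and
Geometric(1/6) degrees (both mean 5, sds 2.2 and 5.5), $\beta = 3/2$,
$\gamma = 1$, $\omega \in \{0, 1, 2\}$, $N = 1000$, NSW graphs, and a
major-outbreak threshold of $0.15N$. The outbreak-probability scenarios use
a **single** initial infective: the probabilities being reproduced are
per-introduction quantities and match the single-ancestor branching fixed
point ($0.61$ vs $0.601$ simulated for the Poisson dropping cell);
probabilities for $n$ independent introductions follow as $1 - q^n$.
The temporal scenarios initialize 5% of the population infective, chosen
uniformly, matching the CLT's random-initial-condition covariance.

Simulations draw degrees from the truncated pmf. This is the same law the
deterministic and fluctuation machinery uses, making every
simulation-vs-theory comparison internally consistent; for the tail masses
involved (under $10^{-4}$) the difference from sampling the untruncated law
is far below Monte-Carlo resolution at the replicate counts used.

Test problem sizes are chosen so the whole suite runs in well under a
minute: oracle comparisons use 20,000 replicates on ≤8-stub
configurations; backend equivalence uses $N \le 300$; the
trajectory-vs-CLT comparison uses $N = 5000$ with 300 replicates at four
checkpoints (and $N = 1000$ with 400 replicates for the band check); the
outbreak-probability check uses 2,000 replicates, which resolves the
printed probabilities to about $\pm 0.022$. The acceptance script uses
10,000 replicates per cell, matching the study's resolution.

Passing tests show the implementation is internally consistent and
reproduces the asymptotic theory at these sizes. They do not show that
real contact networks look like configuration models, that infectious
periods are exponential, or that dropped contacts are never rewired —
see the limitations below.

## Known limitations

* Dropped edges are gone for good: no rewiring to new contacts and no
  temporary deactivation. Rewiring changes the analysis substantially and
  is out of scope.
* Exponential infectious periods only (Markov dynamics throughout).
* Bounded degrees: heavy-tailed laws can only be handled by truncation.
* The Gaussian (CLT) approximation of the *spread* of the prevalence is
  noticeably optimistic at moderate $N$ (hundreds) around and after the
  epidemic peak, even though the LLN mean is excellent almost everywhere;
  final-size approximations are accurate from $N$ in the low hundreds.
* The invariance between the dropping model and the increased-recovery
  model covers the total susceptible trajectory, $R_0$, $r$ and the final
  size — not the composition of susceptibles by effective degree, the
  infective trajectory, outbreak probabilities, or variances. The per-degree
  susceptible fractions genuinely differ between the two models (warnings
  erode susceptible stubs only under dropping), and the test suite pins
  this down.

## A compact tour

```{r tour, eval = FALSE}
poi <- truncate_degree("poisson", 5, 15)
drop <- epidemic_params(1.5, 1, 2)

final_size(drop, poi)                          # rho = 0.676
sigma2_nsw(drop, poi)                          # sigma2_MR + sigma0^2
p_major(drop, poi, "dropping")                 # 0.611 per introduction

ds <- proportional_deficit(poi, 0.05)          # 5% initially infective
sol <- solve_real_time(epidemic_params(1.5, 1, 1), ds, t_end = 5)
cov <- solve_covariance(epidemic_params(1.5, 1, 1), ds,
                        Sigma0 = nsw_initial_covariance(poi, 0.05),
                        t_end = 5, variant = "real")

set.seed(1)
estimate_major_outbreak(drop, poi, N = 1000, i0 = 1, n_reps = 2000)
```
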