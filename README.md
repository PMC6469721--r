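# edgedrop

SIR epidemics on configuration-model networks with preventive dropping of
edges: exact stochastic simulation, deterministic limits, Gaussian
fluctuation theory, final-size asymptotics, and branching-process
approximations.

## The model

A population of `N` individuals forms a random network by the configuration
model: each individual receives a number of half-edges ("stubs") from a
degree distribution `D` (deterministic counts — the Molloy–Reed graph — or
iid degrees — the Newman–Strogatz–Watts graph) and stubs are paired
uniformly at random. A Markovian SIR epidemic spreads on the network:
infectives transmit along each edge at rate `β` and recover at rate `γ`.
The behavioural twist is *preventive dropping*: a susceptible severs its
edge to an infectious neighbour at rate `ω` per edge (equivalently, the
infective warns each neighbour independently at rate `ω`, and warned
susceptibles drop the edge). Dropping makes the network adaptive — it
co-evolves with the epidemic.

The threshold parameter is

    R0 = β/(β+γ+ω) · (μ_D + σ²_D/μ_D − 1),

which depends on `(γ, ω)` only through their sum. The package computes, for
both graph versions:

- **Exact simulation** via the effective-degree Markov chain (the network is
  paired up only as transmission and warning events occur), plus an
  explicit-graph reference backend and a brute-force exact enumerator for
  tiny configurations.
- **The deterministic (LLN) limit**: the effective-degree ODE system in real
  time, its autonomous time-transformed counterpart with closed-form
  solutions, the time change `ξ(t)` linking the two, and the edge-based
  variable `θ(t)`.
- **Final size**: the attack rate `ρ = 1 − f_D(s)` with `s` the root in
  `[0,1)` of `(β+ω+γ)s − (ω+γ) = β f_D'(s)/μ_D`, and its specialization to
  the giant component (`γ = ω = 0`).
- **Fluctuations (CLT)**: the covariance ODE
  `dΣ/dt = G + ∂F Σ + Σ ∂Fᵀ` along the deterministic path, random initial
  covariance for NSW graphs, and the hitting-time projection that yields the
  final-size variance; near-explicit formulas `σ²_MR` and
  `σ²_NSW = σ²_MR + σ₀²`, with fully explicit special cases for `ω = 0` and
  for the giant component.
- **Branching approximation** of the early epidemic: mixed-binomial offspring
  laws, the Malthusian parameter, and major-outbreak probabilities — with the
  ordering that dropping (independent warnings) gives a *higher* outbreak
  probability than the matched model with recovery rate `γ+ω` and no
  dropping, even though both share `R0`, the deterministic susceptible
  trajectory, and the final size.

## Worked example

Poisson(5) degrees, `β = 3/2`, `γ = 1`, `ω = 2`, and the matched
increased-recovery model `(γ+ω, 0)`:

```r
library(edgedrop)
poi <- truncate_degree("poisson", 5, 15)
drop <- epidemic_params(1.5, 1, 2)

final_size(drop, poi)
#> Deterministic final size: rho = 0.675757 (supercritical), s = 0.77474776, z = 0.47441143, tau~ = 0.213052

sqrt(1000 * sigma2_nsw(drop, poi)$sigma2_nsw)          # dropping, NSW graph
#> [1] 32.02636
sqrt(1000 * sigma2_nodropping(1.5, 3, poi, "NSW"))     # increased recovery
#> [1] 37.12399

p_major(drop, poi, "dropping")$p_major
#> [1] 0.6107641
p_major(drop, poi, "modified")$p_major
#> [1] 0.4855128

set.seed(1)
est <- estimate_major_outbreak(drop, poi, N = 1000, i0 = 1, n_reps = 2000)
est$p_hat
#> [1] 0.6095
```

In a population of 1000 a major outbreak (final size above `0.15 N`) occurs
in about 61% of single introductions and then infects about
`1000 × 0.676 ≈ 676` individuals, with a standard deviation of about 32 on
an NSW graph. Replacing dropping by faster recovery leaves the expected
final size unchanged but makes outbreaks rarer (49%) and more variable
(sd ≈ 37): independent per-edge warnings average out part of the
infectious-period randomness.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/edgedrop.R finalsize --beta 1.5 --gamma 1 --omega 2
Rscript inst/cli/edgedrop.R simulate --scenario table1_poisson_dropping --reps 1000 --seed 7 --out runs.json
Rscript inst/cli/edgedrop.R table --reps 2000 --seed 7 --out table.csv
```

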