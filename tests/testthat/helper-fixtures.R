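# Shared fixtures: the two degree families of the numerical study and the
# standard rate sets.

poi5 <- function(kmax = 15) truncate_degree("poisson", 5, kmax)
geo6 <- function(kmax = 50) truncate_degree("geometric", 1 / 6, kmax)

params_drop <- function() epidemic_params(1.5, 1, 2)    # dropping model
params_mod <- function() epidemic_params(1.5, 3, 0)     # increased recovery
params_mid <- function() epidemic_params(1.5, 1, 1)     # temporal-study rates

# deterministic two-point degree law p_1 = p_3 = 1/2
two_point <- function() degree_dist(c(0, 0.5, 0, 0.5))

resolve_scenario_for_test <- function(cfg) edgedrop:::resolve_scenario(cfg)

# one-sided derivative at s = 1 from inside [0, 1]: 5-point stencils at two
# step sizes, Richardson-combined (the PGFs of heavy-ish degree laws have
# large higher derivatives at 1, so a single stencil is not enough)
pgf_deriv_at_1 <- function(f, h = 2e-3) {
  d5 <- function(h) {
    (25 * f(1) - 48 * f(1 - h) + 36 * f(1 - 2 * h) -
       16 * f(1 - 3 * h) + 3 * f(1 - 4 * h)) / (12 * h)
  }
  (16 * d5(h / 2) - d5(h)) / 15
}

dist_mu_for_test <- function(d) sum((0:d$kmax) * d$pmf)
dist_sigma2_for_test <- function(d) {
  k <- 0:d$kmax
  sum(k^2 * d$pmf) - sum(k * d$pmf)^2
}

random_state <- function(M) {
  w <- abs(stats::rnorm(2 * M + 3))
  w / sum(w)
}
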