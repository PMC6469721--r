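test_that("reproduction number and growth rate match hand arithmetic", {
  d <- poi5()
  p <- params_mid()
  # Poisson(5): mu = sigma2 = 5, so R0 = (1.5/3.5) * 5 and r = 1.5*4 - 2
  expect_equal(basic_reproduction_number(p, d), 15 / 7, tolerance = 1e-12)
  expect_equal(malthusian_r(p, d), 4, tolerance = 1e-12)
  # invariance under (gamma, omega) -> (gamma + omega, 0)
  expect_identical(basic_reproduction_number(p, d),
                   basic_reproduction_number(modified_params(p), d))
  # monotone decreasing in omega
  r0s <- vapply(seq(0, 3, 0.5), function(om)
    basic_reproduction_number(epidemic_params(1.5, 1, om), d), numeric(1))
  expect_true(all(diff(r0s) < 0))
})

test_that("Malthusian parameter solves the Euler-Lotka equation", {
  set.seed(401)
  for (rep in 1:8) {
    beta <- runif(1, 0.5, 2.5); gamma <- runif(1, 0.2, 2)
    omega <- runif(1, 0, 2)
    d <- if (rep %% 2 == 0) poi5() else geo6()
    p <- epidemic_params(beta, gamma, omega)
    r <- malthusian_r(p, d, pgf_method = "pmf")
    mu <- dist_mu_for_test(d); s2 <- dist_sigma2_for_test(d)
    el <- (mu - 1 + s2 / mu) * beta / (beta + gamma + omega + r)
    expect_equal(el, 1, tolerance = 1e-10)
    expect_equal(sign(r),
                 sign(basic_reproduction_number(p, d, pgf_method = "pmf") - 1))
  }
})

test_that("offspring laws have the shared mean and ordered variances", {
  p <- epidemic_params(1, 1, 1)
  for (k in c(0, 1, 2, 5, 10)) {
    mo_d <- offspring_moments(k, p, "dropping")
    mo_m <- offspring_moments(k, p, "modified")
    expect_equal(mo_d$mean, k / 3, tolerance = 1e-12)
    expect_equal(mo_m$mean, k / 3, tolerance = 1e-12)
    if (k >= 2) expect_lt(mo_d$variance, mo_m$variance)
    if (k <= 1) expect_equal(mo_d$variance, mo_m$variance, tolerance = 1e-12)
  }
  # k = 1 is Bernoulli(beta/(beta+gamma+omega)) for both models
  expect_equal(offspring_pmf(1, p, "dropping"), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_equal(offspring_pmf(1, p, "modified"), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("offspring PGFs: boundary values, derivative at 1, and ordering", {
  p <- epidemic_params(1.3, 0.8, 0.9)
  s <- seq(0, 1, by = 0.05)
  for (k in c(0, 1, 2, 5, 12)) {
    f_d <- offspring_pgf(k, s, p, "dropping")
    f_m <- offspring_pgf(k, s, p, "modified")
    expect_equal(f_d[length(s)], 1, tolerance = 1e-12)
    expect_equal(f_m[length(s)], 1, tolerance = 1e-12)
    if (k == 0) {
      expect_true(all(f_d == 1) && all(f_m == 1))
      next
    }
    # derivative at s = 1 (5-point stencil): k beta / (beta+gamma+omega)
    h <- 1e-3
    d5 <- function(f) (25 * f(1) - 48 * f(1 - h) + 36 * f(1 - 2 * h) -
                         16 * f(1 - 3 * h) + 3 * f(1 - 4 * h)) / (12 * h)
    expect_equal(d5(function(u) offspring_pgf(k, u, p, "dropping")),
                 k * p$beta / (p$beta + p$gamma + p$omega), tolerance = 1e-7)
    expect_equal(d5(function(u) offspring_pgf(k, u, p, "modified")),
                 k * p$beta / (p$beta + p$gamma + p$omega), tolerance = 1e-7)
    # dropping PGF lies below the modified PGF, strictly inside [0,1) for k>=2
    expect_true(all(f_d <= f_m + 1e-12))
    if (k >= 2) expect_true(all((f_d < f_m)[s < 1]))
  }
  # pgf is the generating function of the pmf
  pmf5 <- offspring_pmf(5, p, "dropping")
  expect_equal(offspring_pgf(5, c(0.2, 0.9), p, "dropping"),
               vapply(c(0.2, 0.9), function(si) sum(pmf5 * si^(0:5)),
                      numeric(1)),
               tolerance = 1e-10)
})

test_that("offspring pmf matches direct mechanism simulation", {
  p <- epidemic_params(1, 1, 1)
  k <- 3
  set.seed(402)
  nmc <- 1e5
  I <- stats::rexp(nmc, p$gamma)
  counts <- vapply(seq_len(nmc), function(m) {
    t_inf <- stats::rexp(k, p$beta)   # per-edge transmission times
    t_drop <- stats::rexp(k, p$omega) # per-edge warning times
    sum(t_inf < pmin(I[m], t_drop))
  }, numeric(1))
  emp <- tabulate(counts + 1, nbins = k + 1) / nmc
  thr <- offspring_pmf(k, p, "dropping")
  for (y in 0:k) {
    se <- sqrt(thr[y + 1] * (1 - thr[y + 1]) / nmc)
    expect_lt(abs(emp[y + 1] - thr[y + 1]), 4 * se)
  }
})

test_that("major-outbreak probability: threshold, ordering, derivative", {
  d <- poi5()
  # subcritical: extinction is certain
  expect_equal(p_major(epidemic_params(0.2, 1, 1), d, "dropping")$p_major, 0)
  set.seed(403)
  for (rep in 1:6) {
    beta <- runif(1, 1, 2.5); gamma <- runif(1, 0.2, 1); omega <- runif(1, 0.3, 2)
    p <- epidemic_params(beta, gamma, omega)
    dd <- if (rep %% 2 == 0) poi5() else geo6()
    if (basic_reproduction_number(p, dd) <= 1.05) next
    bd <- p_major(p, dd, "dropping")
    bm <- p_major(p, dd, "modified")
    expect_gt(bd$p_major, bm$p_major)        # dropping model outbreak is likelier
    expect_lt(bd$sigma_fp, bm$sigma_fp)      # and its chains die out less often
    # derivative of the non-initial mixture PGF at 1 equals R0
    for (model in c("dropping", "modified")) {
      ptil <- size_biased_minus_one(dd)
      ftilde <- function(s) {
        sum(ptil$pmf * vapply(0:ptil$kmax, function(k)
          offspring_pgf(k, s, p, model), numeric(1)))
      }
      expect_equal(pgf_deriv_at_1(ftilde),
                   basic_reproduction_number(p, dd, pgf_method = "pmf"),
                   tolerance = 1e-9)
    }
  }
})

test_that("branching probability agrees with stochastic simulation", {
  d <- poi5()
  p <- params_drop()
  b <- p_major(p, d, "dropping", n_initial = 1)
  set.seed(404)
  est <- estimate_major_outbreak(p, d, 2000, 1, 1500, mode = "NSW")
  se <- sqrt(b$p_major * (1 - b$p_major) / 1500)
  expect_lt(abs(est$p_hat - b$p_major), 3 * se + 0.01)
  # several independent introductions raise the outbreak probability
  b5 <- p_major(p, d, "dropping", n_initial = 5)
  expect_equal(b5$p_major, 1 - b$extinction_single^5, tolerance = 1e-12)
  expect_gt(b5$p_major, b$p_major)
  # degree-specified initial infective
  b0 <- p_major(p, d, "dropping", initial_degree = 0)
  expect_equal(b0$p_major, 0, tolerance = 1e-12)
})
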