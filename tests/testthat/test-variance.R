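test_that("no-dropping closed form specializes the general quadrature route", {
  sets <- list(
    list(beta = 1.5, gamma = 3, d = poi5()),
    list(beta = 1.5, gamma = 3, d = geo6()),
    list(beta = 2, gamma = 1, d = poi5()),
    list(beta = 1, gamma = 0.4, d = geo6()))
  for (s in sets) {
    quad <- sigma2_mr(epidemic_params(s$beta, s$gamma, 0), s$d)$sigma2_mr
    closed <- sigma2_nodropping(s$beta, s$gamma, s$d, "MR")
    expect_equal(quad, closed, tolerance = 1e-8)
  }
  # and with an explicit initial deficit
  ds <- proportional_deficit(poi5(), 0.03)
  quad <- sigma2_mr(epidemic_params(1.5, 2, 0), ds, pgf_method = "pmf")$sigma2_mr
  closed <- sigma2_nodropping(1.5, 2, ds, "MR", pgf_method = "pmf")
  expect_equal(quad, closed, tolerance = 1e-8)
})

test_that("no removal at all reduces to the giant-component variances", {
  d <- poi5()
  p <- epidemic_params(1.7, 0, 0)
  expect_equal(sigma2_mr(p, d)$sigma2_mr, giant_component_variance(d, "MR"),
               tolerance = 1e-8)
  expect_equal(sigma2_nsw(p, d)$sigma2_nsw, giant_component_variance(d, "NSW"),
               tolerance = 1e-8)
  # continuity of the no-dropping closed forms as gamma -> 0
  expect_equal(sigma2_nodropping(1.5, 1e-6, d, "MR"),
               giant_component_variance(d, "MR"), tolerance = 1e-4)
  expect_equal(sigma2_nodropping(1.5, 1e-6, d, "NSW"),
               giant_component_variance(d, "NSW"), tolerance = 1e-4)
})

test_that("NSW no-dropping closed form is MR plus the degree contribution", {
  for (d in list(poi5(), geo6())) {
    p <- epidemic_params(1.5, 3, 0)
    expect_equal(sigma2_nodropping(1.5, 3, d, "NSW"),
                 sigma2_nodropping(1.5, 3, d, "MR") + sigma2_0(p, d),
                 tolerance = 1e-8)
    expect_equal(sigma2_nsw(p, d)$sigma2_nsw,
                 sigma2_nodropping(1.5, 3, d, "NSW"), tolerance = 1e-8)
  }
})

test_that("quadrature terms match midpoint-rule brute force", {
  d <- poi5()
  p <- params_drop()
  v <- sigma2_mr(p, d)
  z <- v$z; b <- v$b
  pw <- p$p_omega; beta <- p$beta; gamma <- p$gamma; omega <- p$omega
  bw <- beta + omega
  vv <- z + (1:1e5 - 0.5) * (1 - z) / 1e5
  h <- (1 - z) / 1e5
  psi1 <- pw + (1 - pw) * z / vv
  psi2 <- vv * psi1^2 + pw * (1 - vv)
  psi3 <- psi1 - b * z / vv
  fd <- function(s, r) pgf_deriv(d, s, r)
  I_A <- sum((omega * (psi3 - 1)^2 + beta * psi3^2) * fd(psi2, 1)) * h / bw
  I_B <- 2 * omega * z * b / bw *
    sum(psi1 * (psi1 - 1) * (1 - psi3) * fd(psi2, 2)) * h
  I_C <- beta * z * b / bw *
    sum(psi1^2 * (b * z / vv - 2 * psi3) * fd(psi2, 2)) * h
  I_D <- z^2 * b^2 / bw *
    sum((omega * (psi1 - 1)^2 + beta * psi1^2) * psi1^2 * fd(psi2, 3)) * h
  expect_equal(v$components$I_A, I_A, tolerance = 1e-7)
  expect_equal(v$components$I_B, I_B, tolerance = 1e-7)
  expect_equal(v$components$I_C, I_C, tolerance = 1e-7)
  expect_equal(v$components$I_D, I_D, tolerance = 1e-7)
})

test_that("degree-randomness contribution is non-negative and additive", {
  d <- poi5()
  for (om in seq(0, 2, by = 0.5)) {
    for (gam in c(0.5, 1, 1.5)) {
      p <- epidemic_params(1.5, gam, om)
      if (basic_reproduction_number(p, d) <= 1) next
      s0 <- sigma2_0(p, d)
      expect_gte(s0, 0)
      v <- sigma2_nsw(p, d)
      expect_gte(v$sigma2_nsw, v$sigma2_mr)
      expect_equal(v$sigma2_nsw, v$sigma2_mr + s0, tolerance = 1e-12)
    }
  }
})

test_that("degree-randomness contribution matches a resampling estimate", {
  d <- poi5()
  p <- params_drop()
  fs <- final_size(p, d, pgf_method = "pmf")
  z <- fs$z; s <- fs$s_root
  mu <- pgf_deriv(d, 1, 1, method = "pmf")
  bwg <- p$beta + p$omega + p$gamma; bw <- p$beta + p$omega
  q <- (bwg * z - p$gamma) / bw
  b <- p$beta * q * mu /
    (z * (p$beta * pgf_deriv(d, s, 2, method = "pmf") - bwg * mu))
  set.seed(202)
  Nn <- 20000; R <- 400
  stat <- replicate(R, {
    D <- sample(0:d$kmax, Nn, TRUE, d$pmf)
    xs <- mean(s^D)
    muN <- mean(D)
    fpN <- mean(D * s^pmax(D - 1, 0))
    yE <- (bwg / bw) * muN * z^2 - (p$gamma / bw) * muN * z - z * fpN
    xs + b * yE
  })
  mc <- Nn * stats::var(stat)
  se <- mc * sqrt(2 / (R - 1))
  expect_lt(abs(mc - sigma2_0(p, d, pgf_method = "pmf")), 3 * se)
})

test_that("giant-component variance guards and ordering hold", {
  expect_error(giant_component_variance(degree_dist(c(0, 1))), "kappa")
  expect_error(giant_component_variance(degree_dist(c(0.1, 0, 0.4, 0.5))),
               "p_1")
  set.seed(203)
  for (r in 1:10) {
    pmf <- c(0.05, 0.15, runif(4))
    pmf <- pmf / sum(pmf)
    d <- degree_dist(pmf)
    if (d$sigma2 + d$mu^2 - 2 * d$mu <= 0) next
    expect_gte(giant_component_variance(d, "NSW"),
               giant_component_variance(d, "MR"))
  }
})

test_that("giant-component sd is confirmed by graph simulation", {
  skip_if_not_installed("igraph")
  d <- poi5()
  set.seed(204)
  N <- 1500; reps <- 250
  sizes <- replicate(reps, {
    deg <- sample(0:d$kmax, N, TRUE, d$pmf)
    if (sum(deg) %% 2 == 1) {
      i <- which(deg > 0)[1]
      deg[i] <- deg[i] - 1
    }
    g <- igraph::sample_degseq(deg, method = "configuration")
    max(igraph::components(g)$csize)
  })
  pred <- sqrt(N * giant_component_variance(d, "NSW"))
  se <- stats::sd(sizes) / sqrt(2 * (reps - 1))
  expect_lt(abs(stats::sd(sizes) - pred), 3 * se + 0.05 * pred)
})

test_that("asymptotic final-size sd agrees with ensemble simulations", {
  set.seed(205)
  N <- 1000
  cases <- list(
    list(p = params_drop(), d = poi5(),
         sd_pred = sqrt(N * sigma2_nsw(params_drop(), poi5())$sigma2_nsw)),
    list(p = params_mod(), d = poi5(),
         sd_pred = sqrt(N * sigma2_nodropping(1.5, 3, poi5(), "NSW"))))
  for (cs in cases) {
    est <- estimate_major_outbreak(cs$p, cs$d, N, 1, 2000, mode = "NSW")
    n <- est$n_major
    # chi-squared sampling band for the empirical sd around the asymptote
    band <- cs$sd_pred * sqrt((n - 1) / stats::qchisq(c(0.995, 0.005), n - 1))
    expect_gt(est$major_sd, band[1])
    expect_lt(est$major_sd, band[2])
    expect_lt(abs(est$major_mean - N * final_size(cs$p, cs$d)$rho),
              4 * est$major_sd / sqrt(n) + 0.01 * N * final_size(cs$p, cs$d)$rho)
  }
})

test_that("unsupported variance regimes raise informative errors", {
  expect_error(sigma2_mr(epidemic_params(0.2, 1, 1), poi5()), "supercritical")
  ds <- proportional_deficit(poi5(), 0.05)
  expect_error(sigma2_0(params_drop(), ds), "eps_E = 0")
  # z = 0 regime
  expect_error(sigma2_mr(epidemic_params(1, 0, 0),
                         degree_dist(c(0.2, 0, 0.5, 0.3))), "z = 0")
})
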