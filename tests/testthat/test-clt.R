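test_that("closed-form drift equals the jump-intensity sum", {
  set.seed(301)
  p <- params_mid()
  for (M in c(4, 10)) {
    for (r in 1:10) {
      w <- random_state(M)
      expect_lt(max(abs(drift(w, p, "real") - drift(w, p, "real", "jumps"))),
                1e-12)
      expect_lt(max(abs(drift(w, p, "transformed") -
                          drift(w, p, "transformed", "jumps"))), 1e-12)
    }
  }
})

test_that("drift vanishes without infectives and z-rate reduces at z = 0", {
  p <- params_mid()
  M <- 6
  w <- c(rep(1 / (M + 1), M + 1), rep(0, M + 1), 0.1)
  expect_equal(drift(w, p, "real"), rep(0, 2 * M + 3))
  # z_E component at z = 0 is exactly gamma * y_E
  w2 <- random_state(M); w2[2 * M + 3] <- 0
  yE <- sum((0:M) * w2[(M + 2):(2 * M + 2)])
  expect_equal(drift(w2, p, "real")[2 * M + 3], p$gamma * yE,
               tolerance = 1e-14)
})

test_that("diffusion matrix is symmetric PSD with the right trace", {
  set.seed(302)
  p <- params_drop()
  M <- 8
  jm <- jump_model(M, p, "real")
  for (r in 1:10) {
    w <- random_state(M)
    G <- diffusion_G(w, p, "real")
    expect_equal(G, t(G))
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
              -1e-9)
    tr <- sum(jm$rates(w) * rowSums(jm$L^2))
    expect_equal(sum(diag(G)), tr, tolerance = 1e-12)
  }
  # no infectives: all intensities vanish
  w0 <- c(rep(1 / (M + 1), M + 1), rep(0, M + 1), 0.05)
  expect_equal(max(abs(diffusion_G(w0, p, "real"))), 0)
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(303)
  p <- epidemic_params(1.2, 0.7, 0.9)
  M <- 7; n <- 2 * M + 3; h <- 1e-6
  for (variant in c("real", "transformed")) {
    for (r in 1:10) {
      w <- random_state(M)
      J <- jacobian_dF(w, p, variant)
      Jfd <- vapply(1:n, function(j) {
        e <- rep(0, n); e[j] <- h
        (drift(w + e, p, variant) - drift(w - e, p, variant)) / (2 * h)
      }, numeric(n))
      expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-5)
    }
  }
  # pure-death structure: with beta = omega = 0 the y-block is -gamma I
  p0 <- epidemic_params(0, 1.3, 0)
  w <- random_state(5)
  J <- jacobian_dF(w, p0, "real")
  expect_equal(J[7:12, 7:12], diag(-1.3, 6), tolerance = 1e-12)
})

test_that("NSW initial covariance has the multinomial structure", {
  d <- poi5()
  S <- nsw_initial_covariance(d, 0.05)
  M <- d$kmax
  expect_equal(S, t(S))
  # the total susceptible and infective counts are non-random given i0
  expect_lt(abs(sum(S[1:(M + 1), 1:(M + 1)])), 1e-12)
  expect_lt(abs(sum(S[(M + 2):(2 * M + 2), (M + 2):(2 * M + 2)])), 1e-12)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
            -1e-12)
  # eps = 0: no infective-block variability
  S0 <- nsw_initial_covariance(d, 0)
  expect_equal(max(abs(S0[(M + 2):(2 * M + 2), (M + 2):(2 * M + 2)])), 0)
})

test_that("covariance ODE keeps Sigma symmetric PSD and matches pure death", {
  d <- truncate_degree("poisson", 2, 6, tail_tol = 0.01)
  ds <- proportional_deficit(d, 0.1)
  p <- params_mid()
  cs <- solve_covariance(p, ds, t_end = 1.5, variant = "real", n_out = 16)
  for (k in c(1, 8, 16)) {
    S <- cs$Sigma[[k]]
    expect_equal(S, t(S), tolerance = 1e-9)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
              -1e-6)
  }
  expect_equal(max(abs(cs$Sigma[[1]])), 0)
  # beta = omega = 0: infective counts are thinned binomials,
  # var(y_i) = eps_i e^{-gamma t}(1 - e^{-gamma t}), independent across i
  p0 <- epidemic_params(0, 1, 0)
  cs0 <- solve_covariance(p0, ds, t_end = 2, variant = "real", n_out = 21)
  surv <- exp(-cs0$time)
  expect_equal(cs0$prevalence_var,
               ds$eps_total * surv * (1 - surv), tolerance = 1e-6)
})

test_that("initial randomness propagates additively", {
  # Sigma solved with Sigma0 equals (solution with 0) + the homogeneous
  # propagation of Sigma0, computed here by solving the homogeneous matrix
  # ODE directly.
  d <- truncate_degree("poisson", 2, 6, tail_tol = 0.01)
  ds <- proportional_deficit(d, 0.1)
  p <- params_mid()
  S0 <- nsw_initial_covariance(d, 0.1)
  n <- 2 * d$kmax + 3
  t_end <- 1.2
  a <- solve_covariance(p, ds, Sigma0 = S0, t_end = t_end, variant = "real",
                        n_out = 7)
  b <- solve_covariance(p, ds, Sigma0 = NULL, t_end = t_end, variant = "real",
                        n_out = 7)
  # homogeneous part: dH = J H + H J^T along the same deterministic path
  rhs <- function(t, st, q) {
    w <- st[1:n]
    H <- matrix(st[-(1:n)], n, n)
    J <- jacobian_dF(w, p, "real")
    list(c(drift(w, p, "real"), J %*% H + H %*% t(J)))
  }
  w0 <- c(ds$pmf - ds$epsilon, ds$epsilon, 0)
  sol <- deSolve::ode(c(w0, as.numeric(S0)), seq(0, t_end, length.out = 7),
                      rhs, NULL, rtol = 1e-8, atol = 1e-10)
  for (k in c(4, 7)) {
    H <- matrix(sol[k, -(1:(n + 1))], n, n)
    expect_lt(max(abs(a$Sigma[[k]] - b$Sigma[[k]] - H)), 1e-7)
  }
})

test_that("hitting-time projection is an oblique projector killing y_E", {
  ds <- proportional_deficit(poi5(), 0.05)
  p <- params_mid()
  cs <- solve_covariance(p, ds, variant = "transformed", stop_at = 0.02)
  k <- length(cs$time)
  w <- cs$w[k, ]
  M <- ds$kmax
  Fw <- drift(w, p, "transformed")
  grad <- c(rep(0, M + 1), 0:M, 0)
  denom <- sum(grad * Fw)
  expect_lt(denom, 0)  # transversal crossing
  B <- diag(length(w)) - outer(Fw, grad) / denom
  expect_lt(max(abs(B %*% B - B)), 1e-10)  # idempotent
  P <- hitting_projection(w, cs$Sigma[[k]], p)
  expect_lt(abs(drop(grad %*% P %*% grad)), 1e-10)  # y_E variance killed
})

test_that("projected covariance route reproduces the variance formula", {
  ds <- proportional_deficit(poi5(), 0.05)
  p <- params_mid()
  o <- sigma2_mr_ode(p, ds, deltas = c(0.05, 0.02, 0.01))
  v <- sigma2_mr(p, ds, pgf_method = "pmf")
  expect_lt(abs(o$sigma2 / v$sigma2_mr - 1), 0.01)
})

test_that("prevalence sd from the covariance ODE matches large-N simulations", {
  d <- poi5()
  ds <- proportional_deficit(d, 0.05)
  p <- params_mid()
  S0 <- nsw_initial_covariance(d, 0.05)
  cs <- solve_covariance(p, ds, Sigma0 = S0, t_end = 2, variant = "real",
                         n_out = 21)
  idx <- c(6, 11, 16, 21)   # t = 0.5, 1, 1.5, 2
  ckpt <- cs$time[idx]
  set.seed(304)
  N <- 5000; reps <- 300
  prev <- matrix(0, reps, length(ckpt))
  for (r in 1:reps) {
    sim <- simulate_epidemic(p, d, N, round(0.05 * N), mode = "NSW",
                             record = TRUE)
    f <- stats::approxfun(sim$trajectory$time, sim$trajectory$infectives,
                          method = "constant", rule = 2)
    prev[r, ] <- f(ckpt)
  }
  mean_pred <- vapply(idx, function(k) sum(cs$w[k, 17:32]), numeric(1))
  sd_pred <- sqrt(cs$prevalence_var[idx])
  sd_obs <- apply(prev, 2, stats::sd) / sqrt(N)
  # means within 4 standard errors of the LLN trajectory
  expect_true(all(abs(colMeans(prev) / N - mean_pred) <=
                    4 * sd_pred / sqrt(N * reps) + 2e-3))
  # sds within 3 sampling standard errors of the CLT prediction
  se_sd <- sd_obs / sqrt(2 * (reps - 1))
  expect_true(all(abs(sd_obs - sd_pred) <= 3 * se_sd + 0.02 * sd_pred))
})
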