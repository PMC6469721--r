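#' Asymptotic final-size variance on a Molloy-Reed graph
#'
#' Evaluates the near-explicit expression for the variance of the scaled
#' final size `T^N / sqrt(N)` of the epidemic with dropping on an MR
#' configuration-model network: four closed-form terms plus four
#' one-dimensional quadratures over `v` in `[z, 1]`, all functions of the
#' root `z` of the final-size equation, the slope factor
#' `b(z) = beta q mu_D / (z [beta f''(psi~(z)) - (beta+omega+gamma) mu_D])`
#' with `q = ((beta+omega+gamma) z - gamma)/(beta+omega)`, and PGF
#' derivatives up to order three. In the trace-of-infection regime
#' (`eps_E = 0`) the proper degree law replaces the deficit law throughout.
#' Requires `z > 0` (equivalently a finite transformed-time extinction time),
#' which fails only when `gamma = omega = 0` and the degree-1 susceptible
#' fraction vanishes.
#'
#' @param params an [epidemic_params()].
#' @param dist a [degree_dist()] (`eps_E = 0` regime, requires `R0 > 1`) or a
#'   [deficit_dist()] with `eps_E > 0`.
#' @param pgf_method see [pgf_deriv()].
#' @return an object of class `variance_result` with `sigma2_mr`, the root
#'   data (`z`, `rho`, `b`), and the individual terms in `components`.
#' @export
sigma2_mr <- function(params, dist, pgf_method = "auto") {
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  bw <- beta + omega; bwg <- beta + omega + gamma
  pw <- params$p_omega
  fs <- final_size(params, dist, pgf_method)
  if (fs$regime == "subcritical")
    stop("variance formulas require a supercritical epidemic (R0 > 1)")
  z <- fs$z
  if (z <= 0)
    stop("z = 0 (infinite transformed extinction time): variance formula does not apply")
  mu <- dist_mu(dist, pgf_method); s2 <- dist_sigma2(dist, pgf_method)
  fd <- function(s, r) pgf_deriv(dist, s, r, method = pgf_method)
  psit <- function(v) pw + (1 - pw) * v   # psi~(v)
  q <- (bwg * z - gamma) / bw
  b <- beta * q * mu / (z * (beta * fd(psit(z), 2) - bwg * mu))

  T1 <- 2 * bwg * (gamma - beta - omega - bwg * z) / bw^2 *
    mu * b^2 * z^2 * (1 - z)
  T2 <- gamma / (beta * bw) * mu * b^2 * z * (beta - (2 * beta + omega) * z)
  T3 <- gamma / (beta * (2 * bw + gamma)) * b^2 * z^2 *
    (beta * (s2 + mu^2) + omega * mu)
  T4 <- -gamma * (bwg * z - gamma) * z / ((2 * bw + gamma) * bw) * mu * b

  psi1 <- function(v) pw + (1 - pw) * z / v
  psi2 <- function(v) v * psi1(v)^2 + pw * (1 - v)
  psi3 <- function(v) psi1(v) - b * z / v
  quad <- function(g) {
    stats::integrate(g, z, 1, rel.tol = 1e-11, abs.tol = 1e-13,
                     subdivisions = 400L)$value
  }
  I_A <- quad(function(v)
    (omega * (psi3(v) - 1)^2 + beta * psi3(v)^2) * fd(psi2(v), 1)) / bw
  I_B <- 2 * omega * z * b / bw * quad(function(v)
    psi1(v) * (psi1(v) - 1) * (1 - psi3(v)) * fd(psi2(v), 2))
  I_C <- beta * z * b / bw * quad(function(v)
    psi1(v)^2 * (b * z / v - 2 * psi3(v)) * fd(psi2(v), 2))
  I_D <- z^2 * b^2 / bw * quad(function(v)
    (omega * (psi1(v) - 1)^2 + beta * psi1(v)^2) * psi1(v)^2 * fd(psi2(v), 3))

  out <- list(
    sigma2_mr = T1 + T2 + T3 + T4 + I_A + I_B + I_C + I_D,
    z = z, rho = fs$rho, b = b, s_root = fs$s_root,
    components = list(T1 = T1, T2 = T2, T3 = T3, T4 = T4,
                      I_A = I_A, I_B = I_B, I_C = I_C, I_D = I_D))
  class(out) <- "variance_result"
  out
}

#' Degree-randomness contribution to the NSW final-size variance
#'
#' On a Newman-Strogatz-Watts graph the degrees themselves are iid, and the
#' randomness of the empirical degree distribution contributes an additional
#' asymptotic variance `sigma0^2` on top of the MR epidemic variance. In the
#' trace-of-infection regime it has the fully explicit closed form in the
#' PGF of `D` evaluated at `psi~(z)` and `psi~(z)^2`.
#'
#' @inheritParams sigma2_mr
#' @param dist a [degree_dist()] (proper law; the `eps_E > 0` case depends on
#'   how initial infectives are chosen and is not covered).
#' @return the scalar `sigma0^2 >= 0`.
#' @export
sigma2_0 <- function(params, dist, pgf_method = "auto") {
  if (inherits(dist, "deficit_dist") && dist$eps_E > 0)
    stop("sigma0^2 is defined for the trace-of-infection regime (eps_E = 0)")
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  bw <- beta + omega; bwg <- beta + omega + gamma
  pw <- params$p_omega
  fs <- final_size(params, dist, pgf_method)
  if (fs$regime == "subcritical") stop("requires R0 > 1")
  z <- fs$z
  if (z <= 0) stop("requires z > 0")
  mu <- dist_mu(dist, pgf_method); s2 <- dist_sigma2(dist, pgf_method)
  fd <- function(s, r) pgf_deriv(dist, s, r, method = pgf_method)
  psi <- pw + (1 - pw) * z
  rho <- fs$rho
  q <- (bwg * z - gamma) / bw
  b <- beta * q * mu / (z * (beta * fd(psi, 2) - bwg * mu))
  fd(psi^2, 0) - (1 - rho)^2 +
    b^2 * psi^2 * z^2 * fd(psi^2, 2) +
    b * fd(psi^2, 1) * z * (z * b - 2 * psi) +
    b^2 * z^2 * q^2 * (s2 + mu^2) -
    2 * b^2 * z^2 * mu * q * (q + (bwg / beta) * psi)
}

#' Asymptotic final-size variance on an NSW graph
#'
#' `sigma2_nsw = sigma2_mr + sigma2_0`: epidemic-process variance plus the
#' degree-randomness contribution. The scaled standard deviation of the
#' final size in a population of size `N` is `sqrt(N * sigma2_nsw)`.
#'
#' @inheritParams sigma2_0
#' @return a `variance_result` with `sigma2_mr`, `sigma2_0` and `sigma2_nsw`.
#' @export
sigma2_nsw <- function(params, dist, pgf_method = "auto") {
  out <- sigma2_mr(params, dist, pgf_method)
  out$sigma2_0 <- sigma2_0(params, dist, pgf_method)
  out$sigma2_nsw <- out$sigma2_mr + out$sigma2_0
  out
}

#' @export
print.variance_result <- function(x, ...) {
  cat(sprintf("Asymptotic final-size variance: sigma2_MR = %.6g", x$sigma2_mr))
  if (!is.null(x$sigma2_nsw))
    cat(sprintf(", sigma2_0 = %.6g, sigma2_NSW = %.6g",
                x$sigma2_0, x$sigma2_nsw))
  cat(sprintf("\n  at z = %.6g, rho = %.6g\n", x$z, x$rho))
  invisible(x)
}

#' Final-size variance of the classical network SIR epidemic
#'
#' Fully explicit asymptotic variances for the no-dropping special case
#' (`omega = 0`). For the MR graph the quadrature terms of the general
#' formula collapse (via the substitution `u = z^2/v`) to antiderivatives in
#' the PGF at `z` and `z^2`; for the NSW graph the closed form uses
#' `h(beta, gamma, z) = (gamma - (beta+gamma) z) /
#' (beta + gamma - beta f''(z)/mu_D)` (which equals `z b(z)`).
#'
#' @param beta,gamma infection and recovery rates.
#' @param dist a [degree_dist()] (or [deficit_dist()] for the MR graph with
#'   `eps_E > 0`).
#' @param graph `"MR"` or `"NSW"`.
#' @inheritParams sigma2_mr
#' @return the scalar asymptotic variance.
#' @export
sigma2_nodropping <- function(beta, gamma, dist, graph = c("MR", "NSW"),
                              pgf_method = "auto") {
  graph <- match.arg(graph)
  params <- epidemic_params(beta, gamma, 0)
  fs <- final_size(params, dist, pgf_method)
  if (fs$regime == "subcritical") stop("requires R0 > 1")
  z <- fs$z
  if (z <= 0) stop("requires z > 0")
  mu <- dist_mu(dist, pgf_method); s2 <- dist_sigma2(dist, pgf_method)
  fd <- function(s, r) pgf_deriv(dist, s, r, method = pgf_method)
  bg <- beta + gamma
  if (graph == "MR") {
    b <- (bg * z - gamma) * mu / (z * (beta * fd(z, 2) - bg * mu))
    T1 <- 2 * bg * (gamma - beta - bg * z) / beta^2 * mu * b^2 * z^2 * (1 - z)
    T2 <- gamma / beta * mu * b^2 * z * (1 - 2 * z)
    T3 <- gamma * b^2 * z^2 * (s2 + mu^2) / (2 * beta + gamma)
    T4 <- -gamma * (bg * z - gamma) * z * mu * b / ((2 * beta + gamma) * beta)
    I_A <- (1 - b)^2 * (fd(z, 0) - fd(z^2, 0))
    I_C <- b * (3 * b - 2) *
      (z * fd(z, 1) - fd(z, 0) - z^2 * fd(z^2, 1) + fd(z^2, 0))
    I_D <- b^2 * (z^2 * fd(z, 2) - 2 * z * fd(z, 1) + 2 * fd(z, 0) -
                    z^4 * fd(z^2, 2) + 2 * z^2 * fd(z^2, 1) - 2 * fd(z^2, 0))
    T1 + T2 + T3 + T4 + I_A + I_C + I_D
  } else {
    if (inherits(dist, "deficit_dist") && dist$eps_E > 0)
      stop("the NSW closed form covers the trace-of-infection regime only")
    rho <- fs$rho
    h <- (gamma - bg * z) / (bg - beta * fd(z, 2) / mu)
    g <- (gamma - bg * z) / beta
    rho * (1 - rho) +
      2 * h * g * (bg / (2 * beta + gamma)) * mu +
      h^2 * (gamma / (2 * beta + gamma) + g^2) * (s2 + mu^2) +
      2 * h^2 * bg * (gamma - bg * z) * z * mu / beta^2
  }
}

#' Asymptotic variance of the giant-component size
#'
#' Closed forms for the variance of the scaled size of the giant component
#' of MR and NSW configuration-model graphs, obtained from the epidemic
#' variances in the limit of no recovery and no dropping. Requires
#' `kappa = E[D(D-2)] > 0` (a giant component exists), `p_1 > 0` and finite
#' maximum degree.
#'
#' @inheritParams sigma2_nodropping
#' @export
giant_component_variance <- function(dist, graph = c("MR", "NSW"),
                                     pgf_method = "auto") {
  graph <- match.arg(graph)
  mu <- dist_mu(dist, pgf_method); s2 <- dist_sigma2(dist, pgf_method)
  kappa <- s2 + mu^2 - 2 * mu
  if (kappa <= 0) stop("no giant component: kappa = E[D(D-2)] <= 0")
  if (dist$pmf[2] <= 0) stop("the giant-component CLT requires p_1 > 0")
  fs <- giant_component_size(dist, pgf_method)
  z <- fs$z; rho <- fs$rho
  fd <- function(s, r) pgf_deriv(dist, s, r, method = pgf_method)
  den <- 1 - fd(z, 2) / mu
  if (graph == "MR") {
    1 - rho - fd(z^2, 0) -
      z^2 / den * (2 * fd(z^2, 1) - mu) -
      z^2 / den^2 * (fd(z^2, 1) + z^2 * fd(z^2, 2) - 2 * mu * z^2)
  } else {
    rho * (1 - rho) + z^2 * mu / den + z^4 * kappa / den^2
  }
}
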