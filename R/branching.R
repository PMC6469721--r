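# Early-stage branching-process approximation. An infective with k
# susceptible neighbours infects a MixBin(k, (beta/(beta+omega))
# (1 - e^{-(beta+omega) I})) number of them, I ~ Exp(gamma) (dropping
# model); the modified model replaces (gamma, omega) by (gamma + omega, 0).

#' Malthusian growth rate of the early epidemic
#'
#' Real root of the Euler-Lotka equation for the early exponential growth,
#' `beta (mu_D - 2 + sigma2_D/mu_D) - gamma - omega`. Its sign agrees
#' with the sign of `R0 - 1`.
#'
#' @inheritParams basic_reproduction_number
#' @export
malthusian_r <- function(params, dist, pgf_method = "auto") {
  mu <- dist_mu(dist, pgf_method); s2 <- dist_sigma2(dist, pgf_method)
  if (mu <= 0) stop("mean degree must be positive")
  params$beta * (mu - 2 + s2 / mu) - params$gamma - params$omega
}

offspring_constants <- function(params, model) {
  beta <- params$beta
  if (model == "dropping") {
    haz <- beta + params$omega     # per-edge disappearance rate while infectious
    grate <- params$gamma          # infectious period rate
    a0 <- if (haz > 0) beta / haz else 0
  } else {
    haz <- beta
    grate <- params$gamma + params$omega
    a0 <- if (beta > 0) 1 else 0
  }
  list(haz = haz, grate = grate, a0 = a0)
}

#' Offspring PGF of an infective with k susceptible neighbours
#'
#' `E[s^Y_k]` for the mixed-binomial offspring law, reduced to the exact
#' finite sum `sum_m C(k,m) a^m (1-a)^{k-m} g/(g + h m)` with
#' `a = beta(1-s)/(beta+omega)`, `h = beta+omega`, `g = gamma` (dropping
#' model) and `a = 1-s`, `h = beta`, `g = gamma+omega` (modified model).
#' The sum has all-positive terms, so it is numerically stable for large k.
#'
#' @param k number of susceptible neighbours.
#' @param s evaluation points in `[0, 1]` (vectorized).
#' @param params an [epidemic_params()].
#' @param model `"dropping"` or `"modified"`.
#' @export
offspring_pgf <- function(k, s, params, model = c("dropping", "modified")) {
  model <- match.arg(model)
  stopifnot(k >= 0, k == round(k), all(s >= 0 & s <= 1))
  if (k == 0) return(rep(1, length(s)))
  cst <- offspring_constants(params, model)
  if (cst$haz == 0) return(rep(1, length(s)))  # beta = 0 (and omega = 0): no offspring
  m <- 0:k
  wgt <- cst$grate / (cst$grate + cst$haz * m)
  vapply(s, function(si) {
    a <- cst$a0 * (1 - si)
    sum(stats::dbinom(m, k, a) * wgt)
  }, numeric(1))
}

#' Offspring pmf of an infective with k susceptible neighbours
#'
#' Exact probabilities `P(Y_k = y)`, computed by integrating the conditional
#' binomial against the law of `V = e^{-h I}` (which has density
#' `c v^{c-1}` on `(0,1)` with `c = g/h`): `P(Y_k = y) = C(k,y) a0^y c
#' int_0^1 v^{c-1} (1-v)^y (1 - a0(1-v))^{k-y} dv`. The integrand is
#' positive and smooth, avoiding the catastrophic cancellation of the
#' alternating-series expansion at large k.
#'
#' @inheritParams offspring_pgf
#' @return numeric vector of probabilities over `y = 0..k`.
#' @export
offspring_pmf <- function(k, params, model = c("dropping", "modified")) {
  model <- match.arg(model)
  stopifnot(k >= 0, k == round(k))
  if (k == 0) return(1)
  cst <- offspring_constants(params, model)
  if (cst$haz == 0 || cst$a0 == 0) return(c(1, rep(0, k)))
  cc <- cst$grate / cst$haz
  a0 <- cst$a0
  p <- vapply(0:k, function(y) {
    integrand <- function(v)
      cc * v^(cc - 1) * (1 - v)^y * (1 - a0 * (1 - v))^(k - y)
    choose(k, y) * a0^y *
      stats::integrate(integrand, 0, 1, rel.tol = 1e-12,
                       abs.tol = 1e-14)$value
  }, numeric(1))
  p / sum(p)
}

#' Mean and variance of the offspring law
#'
#' The mean is `k beta / (beta + gamma + omega)` for both the dropping and
#' the modified model; the variances differ, the dropping model being the
#' less variable for `k >= 2` (independent warnings average out part of the
#' infectious-period randomness).
#'
#' @inheritParams offspring_pmf
#' @return list with `mean` and `variance`.
#' @export
offspring_moments <- function(k, params, model = c("dropping", "modified")) {
  model <- match.arg(model)
  p <- offspring_pmf(k, params, model)
  y <- 0:k
  m <- sum(y * p)
  list(mean = m, variance = sum(y^2 * p) - m^2)
}

#' Probability of a major outbreak
#'
#' Branching-process approximation of the early epidemic: non-initial
#' infectives have `k` susceptible neighbours with the size-biased-minus-one
#' law, so the extinction probability per infection chain is the unique
#' fixed point in `[0, 1)` of `ftilde(s) = sum_k ptilde_k f_k(s)` when
#' `R0 > 1`. The initial infectives have degree distributed as `D` itself
#' (uniform choice) or a specified degree, and a major outbreak occurs when
#' at least one initial infective's chain survives.
#'
#' @param params an [epidemic_params()].
#' @param dist a [degree_dist()].
#' @param model `"dropping"` or `"modified"`.
#' @param n_initial number of initial infectives (independent chains).
#' @param initial_degree if supplied, all initial infectives have exactly
#'   this many susceptible neighbours instead of `D`-distributed degrees.
#' @return an object of class `branching_result` with `R0`, `r`, `sigma_fp`
#'   (the fixed point), `p_major` and `model`.
#' @export
p_major <- function(params, dist, model = c("dropping", "modified"),
                    n_initial = 1, initial_degree = NULL) {
  model <- match.arg(model)
  r0 <- basic_reproduction_number(params, dist, pgf_method = "pmf")
  r <- malthusian_r(params, dist, pgf_method = "pmf")
  out <- list(R0 = r0, r = r, model = model, n_initial = n_initial)
  if (r0 <= 1) {
    out$sigma_fp <- 1
    out$p_major <- 0
    class(out) <- "branching_result"
    return(out)
  }
  ptil <- size_biased_minus_one(dist)
  fk_tab <- function(s) {
    vapply(0:ptil$kmax, function(k) offspring_pgf(k, s, params, model),
           numeric(1))
  }
  ftilde <- function(s) sum(ptil$pmf * fk_tab(s))
  g <- function(s) ftilde(s) - s
  sigma <- stats::uniroot(g, c(0, 1 - 1e-12), tol = 1e-14)$root
  q1 <- if (is.null(initial_degree)) {
    fk0 <- vapply(0:dist$kmax, function(k)
      offspring_pgf(k, sigma, params, model), numeric(1))
    sum(dist$pmf * fk0)
  } else {
    offspring_pgf(initial_degree, sigma, params, model)
  }
  out$sigma_fp <- sigma
  out$extinction_single <- q1
  out$p_major <- 1 - q1^n_initial
  class(out) <- "branching_result"
  out
}

#' @export
print.branching_result <- function(x, ...) {
  cat(sprintf(
    "Branching approximation (%s model): R0 = %.6g, r = %.6g\n",
    x$model, x$R0, x$r))
  cat(sprintf("  fixed point sigma = %.6g, P(major outbreak | %d initial) = %.6g\n",
              x$sigma_fp, x$n_initial, x$p_major))
  invisible(x)
}
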