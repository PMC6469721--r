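#' Degree distributions with finite support
#'
#' A `degree_dist` stores the degree law of the network as a finite pmf
#' `p_0, ..., p_kmax` together with its first two moments and, for the named
#' families, the original parameters so that probability generating function
#' (PGF) derivatives can be evaluated from the analytic closed forms of the
#' untruncated distribution.
#'
#' @param pmf numeric vector of probabilities for degrees `0:(length(pmf)-1)`.
#'   Must be non-negative and sum to 1 within `1e-12` (renormalized exactly).
#' @param family one of `"custom"`, `"poisson"`, `"geometric"`; named families
#'   carry `param` for analytic PGF evaluation.
#' @param param distribution parameter: the mean `lambda` for Poisson, the
#'   success probability `p` for geometric (pmf `p(1-p)^k`, `k >= 0`).
#' @return an object of class `degree_dist` with components `pmf`, `kmax`,
#'   `family`, `param`, `mu` (mean) and `sigma2` (variance).
#' @seealso [truncate_degree()] for building truncated named families,
#'   [pgf_deriv()], [size_biased_minus_one()], [deficit_dist()].
#' @export
degree_dist <- function(pmf, family = "custom", param = NULL) {
  stopifnot(is.numeric(pmf), length(pmf) >= 1L, all(is.finite(pmf)))
  if (any(pmf < 0)) stop("pmf entries must be non-negative")
  s <- sum(pmf)
  if (abs(s - 1) > 1e-12) stop("pmf must sum to 1 within 1e-12 (got ", s, ")")
  pmf <- pmf / s
  k <- seq_along(pmf) - 1
  mu <- sum(k * pmf)
  sigma2 <- sum(k^2 * pmf) - mu^2
  structure(
    list(pmf = pmf, kmax = length(pmf) - 1L, family = family, param = param,
         mu = mu, sigma2 = sigma2),
    class = "degree_dist"
  )
}

#' @export
print.degree_dist <- function(x, ...) {
  fam <- switch(x$family,
    poisson = sprintf("Poisson(%g), truncated at %d", x$param, x$kmax),
    geometric = sprintf("Geometric(%g), truncated at %d", x$param, x$kmax),
    sprintf("custom pmf on 0..%d", x$kmax))
  cat("Degree distribution: ", fam, "\n", sep = "")
  cat(sprintf("  mean %.6g, variance %.6g\n", x$mu, x$sigma2))
  invisible(x)
}

#' Truncate a named degree family to finite support
#'
#' Builds a `degree_dist` by restricting a Poisson or geometric law to
#' `0:kmax` and renormalizing. The effective-degree Markov chain and its
#' deterministic limits require a maximum degree; renormalizing (rather than
#' leaving the lost tail mass unassigned) keeps every pmf invariant exact.
#' A warning is raised when the discarded tail mass exceeds `tail_tol`, so a
#' too-aggressive truncation does not pass silently.
#'
#' @param family `"poisson"` or `"geometric"`.
#' @param param the family parameter (Poisson mean, or geometric success
#'   probability with pmf `p(1-p)^k`).
#' @param kmax truncation point (inclusive); `kmax >= 1`. When `NULL`, the
#'   smallest point with tail mass below `1e-8` is used.
#' @param tail_tol warn if the pre-renormalization mass above `kmax` exceeds
#'   this value.
#' @return a `degree_dist`.
#' @export
truncate_degree <- function(family = c("poisson", "geometric"), param,
                            kmax = NULL, tail_tol = 1e-4) {
  family <- match.arg(family)
  stopifnot(is.finite(param))
  if (is.null(kmax)) {
    kmax <- 1L
    tailmass <- function(m) switch(family,
      poisson = stats::ppois(m, param, lower.tail = FALSE),
      geometric = stats::pgeom(m, param, lower.tail = FALSE))
    while (tailmass(kmax) >= 1e-8) kmax <- kmax + 1L
  }
  stopifnot(kmax >= 1)
  k <- 0:kmax
  pmf <- switch(family,
    poisson = stats::dpois(k, lambda = param),
    geometric = stats::dgeom(k, prob = param))
  tail <- 1 - sum(pmf)
  if (tail > tail_tol) {
    warning(sprintf(
      "truncation at kmax=%d discards tail mass %.3g > tail_tol=%.3g",
      kmax, tail, tail_tol))
  }
  degree_dist(pmf / sum(pmf), family = family, param = param)
}

#' Degree distribution with an initial-infective deficit
#'
#' Encodes the defective law with mass `p_k - epsilon_k` at degree `k`, where
#' `epsilon_k` is the limiting fraction of the population that is initially
#' infective with degree `k`. Its PGF appears throughout the deterministic
#' solutions: the all-zero `epsilon` recovers the proper degree law and encodes
#' the limit of an epidemic started by a trace of infection.
#'
#' @param base a `degree_dist`.
#' @param epsilon numeric vector of length `kmax+1` with `0 <= epsilon_k <= p_k`.
#' @return an object of class `c("deficit_dist", "degree_dist")`; `epsilon`
#'   (total initially-infective fraction) and `epsilon_E` (initially-infective
#'   stub fraction) are stored as components `eps_total` and `eps_E`.
#' @export
deficit_dist <- function(base, epsilon) {
  stopifnot(inherits(base, "degree_dist"), is.numeric(epsilon),
            length(epsilon) == base$kmax + 1L)
  if (any(epsilon < -1e-15) || any(epsilon > base$pmf + 1e-12))
    stop("need 0 <= epsilon_k <= p_k for all k")
  epsilon <- pmin(pmax(epsilon, 0), base$pmf)
  k <- 0:base$kmax
  obj <- base
  obj$epsilon <- epsilon
  obj$eps_total <- sum(epsilon)
  obj$eps_E <- sum(k * epsilon)
  class(obj) <- c("deficit_dist", "degree_dist")
  obj
}

#' Proportional initial-infective deficit
#'
#' Convenience constructor for the standard initial condition in which a
#' fraction `eps` of individuals of every degree is initially infective, i.e.
#' `epsilon_k = eps * p_k`.
#'
#' @param base a `degree_dist`.
#' @param eps initially-infective fraction in `[0, 1)`.
#' @export
proportional_deficit <- function(base, eps) {
  stopifnot(eps >= 0, eps < 1)
  deficit_dist(base, eps * base$pmf)
}

falling_factorial <- function(k, r) {
  # k!/(k-r)! for vectors k, scalar r >= 0; zero when k < r
  out <- rep(1, length(k))
  if (r > 0) for (j in 0:(r - 1)) out <- out * pmax(k - j, 0)
  out
}

#' Evaluate PGF derivatives of a degree distribution
#'
#' Returns the `order`-th derivative of the PGF at `s`, i.e.
#' `sum_k p_k k!/(k-order)! s^(k-order)` (with `p_k - epsilon_k` in place of
#' `p_k` for a [deficit_dist()]). For the named families the analytic closed
#' forms of the untruncated law are available: `lambda^i e^{-lambda(1-s)}`
#' (Poisson) and `i! p (1-p)^i / (1-(1-p)s)^{i+1}` (geometric); the default
#' `method = "auto"` uses them when present, so final-size and variance
#' formulas are evaluated with the exact untruncated PGFs while the truncated
#' pmf drives the finite ODE systems.
#'
#' @param dist a `degree_dist` or `deficit_dist`.
#' @param s evaluation points in `[0, 1]` (vectorized).
#' @param order derivative order, a non-negative integer.
#' @param method `"auto"`, `"analytic"` (named families only) or `"pmf"`
#'   (brute-force sum over the stored truncated pmf).
#' @return numeric vector of the same length as `s`.
#' @export
pgf_deriv <- function(dist, s, order = 0L, method = c("auto", "analytic", "pmf")) {
  method <- match.arg(method)
  stopifnot(inherits(dist, "degree_dist"), order >= 0, order == round(order))
  if (any(s < -1e-12 | s > 1 + 1e-12)) stop("s must lie in [0, 1]")
  s <- pmin(pmax(s, 0), 1)
  use_analytic <- switch(method,
    auto = dist$family %in% c("poisson", "geometric"),
    analytic = TRUE,
    pmf = FALSE)
  if (use_analytic && !dist$family %in% c("poisson", "geometric"))
    stop("analytic PGF formulas are only available for named families")
  base_val <- if (use_analytic) {
    if (dist$family == "poisson") {
      dist$param^order * exp(-dist$param * (1 - s))
    } else {
      p <- dist$param
      factorial(order) * p * (1 - p)^order / (1 - (1 - p) * s)^(order + 1)
    }
  } else {
    pmf_pgf_deriv(dist$pmf, s, order)
  }
  if (inherits(dist, "deficit_dist")) {
    base_val <- base_val - pmf_pgf_deriv(dist$epsilon, s, order, is_pmf = FALSE)
  }
  base_val
}

pmf_pgf_deriv <- function(weights, s, order, is_pmf = TRUE) {
  k <- seq_along(weights) - 1
  coef <- weights * falling_factorial(k, order)
  keep <- k >= order
  if (!any(keep)) return(rep(0, length(s)))
  k <- k[keep]; coef <- coef[keep]
  vapply(s, function(si) sum(coef * si^(k - order)), numeric(1))
}

#' Law of the size-biased degree minus one
#'
#' The degree of a neighbour reached along a uniformly chosen stub has the
#' size-biased law `P(D~ = k) = k p_k / mu`; removing the edge used to reach
#' the neighbour leaves `D~ - 1` further stubs, with pmf
#' `ptilde_k = (k+1) p_{k+1} / mu`. This is the mixing law of the offspring
#' distribution for non-initial cases in the branching approximation.
#'
#' @param dist a `degree_dist` with positive mean.
#' @return a `degree_dist` on `0:(kmax-1)`.
#' @export
size_biased_minus_one <- function(dist) {
  stopifnot(inherits(dist, "degree_dist"))
  if (dist$mu <= 0) stop("degenerate distribution: mean degree is zero")
  k <- 1:dist$kmax
  pmf <- k * dist$pmf[k + 1] / dist$mu
  degree_dist(pmf / sum(pmf), family = "custom")
}
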