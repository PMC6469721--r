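dist_mu <- function(dist, method = "auto") {
  if (method %in% c("auto", "analytic") &&
      dist$family %in% c("poisson", "geometric")) {
    switch(dist$family,
           poisson = dist$param,
           geometric = (1 - dist$param) / dist$param)
  } else {
    sum((0:dist$kmax) * dist$pmf)
  }
}

dist_sigma2 <- function(dist, method = "auto") {
  if (method %in% c("auto", "analytic") &&
      dist$family %in% c("poisson", "geometric")) {
    switch(dist$family,
           poisson = dist$param,
           geometric = (1 - dist$param) / dist$param^2)
  } else {
    k <- 0:dist$kmax
    sum(k^2 * dist$pmf) - sum(k * dist$pmf)^2
  }
}

#' Basic reproduction number
#'
#' `R0 = beta/(beta+gamma+omega) * (mu_D + sigma2_D/mu_D - 1)`: the
#' probability that a given susceptible-infective edge transmits before the
#' infective recovers or the edge is dropped, times the mean number of
#' further stubs of a neighbour reached along a uniformly chosen edge. `R0`
#' depends on `(gamma, omega)` only through their sum, and decreases in the
#' dropping rate.
#'
#' @param params an [epidemic_params()].
#' @param dist a [degree_dist()] with positive mean.
#' @param pgf_method moment evaluation route (see [pgf_deriv()]).
#' @export
basic_reproduction_number <- function(params, dist, pgf_method = "auto") {
  mu <- dist_mu(dist, pgf_method); s2 <- dist_sigma2(dist, pgf_method)
  if (mu <= 0) stop("mean degree must be positive")
  params$beta / (params$beta + params$gamma + params$omega) *
    (mu + s2 / mu - 1)
}

#' Residual of the deterministic final-size equation
#'
#' Signed residual of `(beta+omega+gamma) s - (omega+gamma) =
#' beta f'(s) / mu_D` at `s`, where `f` is the PGF of the degree law (or of
#' the deficit law when `dist` carries initial-infective fractions). The
#' unique root in `[0, 1)` determines the deterministic final size; `s = 1`
#' always solves the equation in the trace-of-infection limit.
#'
#' @param params an [epidemic_params()].
#' @param dist a [degree_dist()] or [deficit_dist()].
#' @param s evaluation points in `[0, 1]`.
#' @inheritParams basic_reproduction_number
#' @export
final_size_residual <- function(params, dist, s, pgf_method = "auto") {
  mu <- dist_mu(dist, pgf_method)
  (params$beta + params$omega + params$gamma) * s -
    (params$omega + params$gamma) -
    params$beta * pgf_deriv(dist, s, 1, method = pgf_method) / mu
}

#' Deterministic final size of the epidemic
#'
#' Computes the fraction `rho` of the population ultimately infected in the
#' large-population deterministic limit: `rho = 1 - f(s)` with `s` the unique
#' root in `[0, 1)` of `(beta+omega+gamma)s - (omega+gamma) =
#' beta f'(s)/mu_D`. For a proper degree law (trace-of-infection limit,
#' `eps_E = 0`) the root below 1 exists iff `R0 > 1`; a subcritical model
#' returns `rho = 0` with `s = 1` by convention. The associated quantities
#' `z = ((beta+omega)s - omega)/beta` (stub-survival variable) and the
#' transformed-time extinction time `tau~ = -log(z)/(beta+omega)` are
#' returned too; the final size depends on `(gamma, omega)` only through
#' `gamma + omega`.
#'
#' @inheritParams final_size_residual
#' @param tol root tolerance (residual is polished to below `1e-12`).
#' @return an object of class `final_size_result` with components `s_root`,
#'   `z`, `rho`, `tau_tilde`, `regime` and `R0` (the latter only meaningful
#'   in the `eps_E = 0` regime).
#' @export
final_size <- function(params, dist, pgf_method = "auto", tol = 1e-12) {
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  mu <- dist_mu(dist, pgf_method)
  eps_E <- if (inherits(dist, "deficit_dist")) dist$eps_E else 0
  r0 <- basic_reproduction_number(params, dist, pgf_method)
  res <- function(s) final_size_residual(params, dist, s, pgf_method)
  if (eps_E == 0 && r0 <= 1) {
    out <- list(s_root = 1, z = 1, rho = 0, tau_tilde = 0,
                regime = "subcritical", R0 = r0)
    class(out) <- "final_size_result"
    return(out)
  }
  lo <- 0
  r_lo <- res(lo)
  if (r_lo >= 0) {
    s <- 0  # happens only when gamma = omega = 0 and p_1 (- eps_1) = 0
  } else {
    hi <- if (eps_E > 0) 1 else {
      h <- 1e-9
      while (res(1 - h) <= 0 && h < 1e-3) h <- h * 10
      1 - h
    }
    s <- stats::uniroot(res, c(lo, hi), tol = 1e-14)$root
    # Newton polish against the analytic derivative of the residual
    for (it in 1:4) {
      dr <- (beta + omega + gamma) -
        beta * pgf_deriv(dist, s, 2, method = pgf_method) / mu
      step <- res(s) / dr
      s_new <- min(max(s - step, 0), 1)
      if (!is.finite(s_new)) break
      s <- s_new
      if (abs(res(s)) < tol) break
    }
  }
  z <- if (beta > 0) max(((beta + omega) * s - omega) / beta, 0) else 0
  out <- list(
    s_root = s,
    z = z,
    rho = 1 - pgf_deriv(dist, s, 0, method = pgf_method),
    tau_tilde = if (z > 0) -log(z) / (beta + omega) else Inf,
    regime = "supercritical",
    R0 = r0)
  class(out) <- "final_size_result"
  out
}

#' @export
print.final_size_result <- function(x, ...) {
  cat(sprintf(
    "Deterministic final size: rho = %.6g (%s), s = %.8g, z = %.8g, tau~ = %.6g\n",
    x$rho, x$regime, x$s_root, x$z, x$tau_tilde))
  invisible(x)
}

#' Asymptotic size of the configuration-model giant component
#'
#' The epidemic with no recovery and no dropping ultimately infects the whole
#' component of each initial infective, so the trace-of-infection final size
#' equals the relative size of the giant component: `rho = 1 - f_D(z)` with
#' `z` the unique root in `[0, 1)` of `mu_D z = f_D'(z)`. A giant component
#' exists iff `kappa = E[D(D-2)] > 0`.
#'
#' @inheritParams final_size_residual
#' @return a `final_size_result` (with `rho = 0` when `kappa <= 0`).
#' @export
giant_component_size <- function(dist, pgf_method = "auto") {
  final_size(epidemic_params(1, 0, 0), dist, pgf_method)
}
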