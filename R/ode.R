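shift_down_weighted <- function(v) {
  # returns the vector with i-th entry (i+1) * v_{i+1}, i = 0..M (v indexed 0..M)
  M <- length(v) - 1L
  c(v[-1] * seq_len(M), 0)
}

det_solution <- function(time, x, y, z_E, variant) {
  M <- ncol(x) - 1L
  i <- 0:M
  xE <- drop(x %*% i); yE <- drop(y %*% i)
  etaE <- xE + yE + z_E
  structure(list(
    time = time, x = x, y = y, z_E = z_E,
    xE = xE, yE = yE, etaE = etaE,
    rhoE = ifelse(etaE > 0, yE / etaE, NA_real_),
    xsum = rowSums(x), ysum = rowSums(y),
    variant = variant, M = M), class = "det_solution")
}

#' @export
print.det_solution <- function(x, ...) {
  cat(sprintf(
    "Deterministic effective-degree solution (%s time), M = %d, %d time points on [0, %.4g]\n",
    x$variant, x$M, length(x$time), max(x$time)))
  cat(sprintf("  final susceptible fraction %.6g, final infective fraction %.6g\n",
              x$xsum[length(x$time)], x$ysum[length(x$time)]))
  invisible(x)
}

ode_initial_state <- function(dspec) {
  if (!inherits(dspec, "deficit_dist"))
    stop("supply a deficit_dist (initial-infective fractions are part of the state)")
  c(dspec$pmf - dspec$epsilon, dspec$epsilon, 0)
}

#' Law-of-large-numbers limit of the epidemic in real time
#'
#' Solves the deterministic effective-degree system: `x_i` (susceptible
#' fraction with `i` unpaired stubs), `y_i` (infective), and `z_E`
#' (recovered-stub fraction), with
#' `dx_i/dt = rho_E [ -beta i x_i + omega(-i x_i + (i+1) x_{i+1}) ]`,
#' `dy_i/dt = (beta+omega)((i+1)y_{i+1} - i y_i)(1 + rho_E) +
#'            beta rho_E (i+1) x_{i+1} - gamma y_i`,
#' `dz_E/dt = gamma y_E - (beta+omega) rho_E z_E`, where
#' `rho_E = y_E / eta_E` is the fraction of unpaired stubs that belong to
#' infectives. Initial condition `(p_i - eps_i, eps_i, 0)`; requires a
#' positive initial infective stub fraction `eps_E`.
#'
#' @param params an [epidemic_params()].
#' @param dspec a [deficit_dist()] with `eps_E > 0`.
#' @param t_end end of the integration interval.
#' @param n_out number of output times.
#' @param rtol,atol solver tolerances.
#' @return a `det_solution`.
#' @export
solve_real_time <- function(params, dspec, t_end, n_out = 201,
                            rtol = 1e-8, atol = 1e-10) {
  if (dspec$eps_E <= 0) stop("the LLN limit requires eps_E > 0")
  w0 <- ode_initial_state(dspec)
  M <- dspec$kmax
  i <- 0:M
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  rhs <- function(t, w, p) {
    x <- w[1:(M + 1)]; y <- w[(M + 2):(2 * M + 2)]; z <- w[2 * M + 3]
    yE <- sum(i * y); etaE <- sum(i * x) + yE + z
    rho <- if (etaE > 0) yE / etaE else 0
    up_x <- shift_down_weighted(x); up_y <- shift_down_weighted(y)
    dx <- rho * (-beta * i * x + omega * (up_x - i * x))
    dy <- (beta + omega) * (up_y - i * y) * (1 + rho) +
      beta * rho * up_x - gamma * y
    dz <- gamma * yE - (beta + omega) * rho * z
    list(c(dx, dy, dz))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(w0, times, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  det_solution(sol[, 1], sol[, 2:(M + 2), drop = FALSE],
               sol[, (M + 3):(2 * M + 3), drop = FALSE], sol[, 2 * M + 4],
               variant = "real")
}

#' Time-transformed deterministic limit
#'
#' Solves the system obtained by running the clock at rate `eta_E / y_E`
#' (one unit of transformed time per unit of integrated stub-prevalence),
#' under which the susceptible block decouples and the total stub fraction
#' decays exactly as `mu_D e^{-2(beta+omega)t}`. Integration stops by event
#' detection at `y_E(t) = delta` (the transformed system leaves the
#' admissible region beyond the hitting time `tau~`), and the hitting time
#' is returned as `tau_delta`.
#'
#' @inheritParams solve_real_time
#' @param delta stop level for the infective stub fraction (`delta = 0`
#'   integrates to the extinction root `tau~` itself).
#' @param n_out output grid resolution before the event.
#' @return a `det_solution` with extra fields `tau_delta` and `hit` (logical:
#'   did the event occur).
#' @export
solve_time_transformed <- function(params, dspec, delta = 0, n_out = 201,
                                   rtol = 1e-8, atol = 1e-10) {
  if (dspec$eps_E <= 0) stop("the LLN limit requires eps_E > 0")
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  if (beta + omega <= 0) stop("time transformation requires beta + omega > 0")
  if (gamma == 0 && omega == 0 &&
      dspec$pmf[2] - dspec$epsilon[2] <= 0 && delta == 0)
    warning("gamma = omega = p_1 - eps_1 = 0: the hitting time tau~ is infinite")
  w0 <- ode_initial_state(dspec)
  M <- dspec$kmax
  i <- 0:M
  rhs <- function(t, w, p) {
    x <- w[1:(M + 1)]; y <- w[(M + 2):(2 * M + 2)]; z <- w[2 * M + 3]
    yE <- sum(i * y); etaE <- sum(i * x) + yE + z
    rho <- yE / etaE
    up_x <- shift_down_weighted(x); up_y <- shift_down_weighted(y)
    dx <- -beta * i * x + omega * (up_x - i * x)
    dy <- ((beta + omega) * (up_y - i * y) - gamma * y) / rho +
      (beta + omega) * (up_y - i * y) + beta * up_x
    dz <- gamma * etaE - (beta + omega) * z
    list(c(dx, dy, dz))
  }
  rootfun <- function(t, w, p) {
    sum(i * w[(M + 2):(2 * M + 2)]) - delta
  }
  # upper time bound from the closed-form hitting time (generous multiple)
  t_cap <- guess_tau_cap(params, dspec, delta)
  times <- seq(0, t_cap, length.out = n_out)
  sol <- deSolve::lsodar(w0, times, rhs, NULL, rtol = rtol, atol = atol,
                         rootfunc = rootfun)
  troot <- attr(sol, "troot")
  out <- det_solution(sol[, 1], sol[, 2:(M + 2), drop = FALSE],
                      sol[, (M + 3):(2 * M + 3), drop = FALSE],
                      sol[, 2 * M + 4], variant = "transformed")
  out$hit <- length(troot) > 0
  out$tau_delta <- if (out$hit) troot[1] else NA_real_
  out
}

guess_tau_cap <- function(params, dspec, delta) {
  bw <- params$beta + params$omega
  f <- function(t) closed_form_tilde(params, dspec, t)$yE - delta
  hi <- 1 / bw
  while (f(hi) > 0 && hi < 1e3 / bw) hi <- hi * 2
  1.25 * hi
}

#' Closed-form solution of the time-transformed susceptible block
#'
#' Evaluates the exact expressions for the transformed-time system: the
#' susceptible fractions by effective degree
#' `x_i(t) = e^{-(beta+omega) i t} / i! * f^(i)(p_omega (1 - e^{-(beta+omega)t}))`,
#' the susceptible stub fraction `x_E = e^{-(beta+omega)t} f'(psi(t))` with
#' `psi(t) = p_omega + (1-p_omega) e^{-(beta+omega)t}`, the total stub
#' fraction `eta_E = mu_D e^{-2(beta+omega)t}`, the recovered-stub fraction
#' `z_E = (gamma/(beta+omega)) mu_D e^{-(beta+omega)t}(1-e^{-(beta+omega)t})`,
#' `y_E = eta_E - x_E - z_E`, and the susceptible fraction `x = f(psi(t))`,
#' where `f` is the PGF of the deficit law.
#'
#' @param params an [epidemic_params()] with `beta + omega > 0`.
#' @param dspec a [deficit_dist()].
#' @param t vector of (transformed) times, `t >= 0`.
#' @param pgf_method PGF evaluation route; the default `"pmf"` matches the
#'   truncated system the ODE solvers integrate.
#' @return a list with `x_i` (matrix, rows = times), `xE`, `etaE`, `zE`,
#'   `yE`, `xsum`, and `psi`.
#' @export
closed_form_tilde <- function(params, dspec, t, pgf_method = "pmf") {
  stopifnot(all(t >= 0))
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  bw <- beta + omega
  if (bw <= 0) stop("closed forms require beta + omega > 0")
  pw <- params$p_omega
  M <- dspec$kmax
  mu <- sum((0:M) * (dspec$pmf))
  e1 <- exp(-bw * t)
  psi <- pw + (1 - pw) * e1
  arg <- pw * (1 - e1)
  x_i <- matrix(0, length(t), M + 1)
  for (i in 0:M) {
    x_i[, i + 1] <- exp(-bw * i * t) / factorial(i) *
      pgf_deriv(dspec, arg, order = i, method = pgf_method)
  }
  xE <- e1 * pgf_deriv(dspec, psi, order = 1, method = pgf_method)
  etaE <- mu * exp(-2 * bw * t)
  zE <- (gamma / bw) * mu * e1 * (1 - e1)
  yE <- etaE - xE - zE
  xsum <- pgf_deriv(dspec, psi, order = 0, method = pgf_method)
  list(x_i = x_i, xE = xE, etaE = etaE, zE = zE, yE = yE,
       xsum = xsum, psi = psi)
}

#' Time change and edge-survival probability
#'
#' Solves jointly for the time change `xi(t)` linking the real-time and
#' transformed-time systems (`w(t) = w~(xi(t))`, with
#' `dxi/dt = 1 + (gamma/(beta+omega))(1 - e^{(beta+omega) xi}) -
#'  e^{(beta+omega) xi} f'(psi(xi))/mu_D`, `xi(0) = 0`) and for the
#' edge-based variable `theta(t)` (probability that no transmission has come
#' down a given edge by time `t`), which satisfies
#' `dtheta/dt = beta f'(theta)/mu_D - (beta+gamma+omega) theta + gamma + omega`,
#' `theta(0) = 1`. The two are linked by the identity `theta(t) = psi(xi(t))`.
#'
#' @inheritParams closed_form_tilde
#' @param t_end end of the real-time grid.
#' @param n_out number of output times.
#' @return a list with `time`, `xi`, `theta` and `psi_of_xi`.
#' @export
solve_xi_theta <- function(params, dspec, t_end, n_out = 201,
                           pgf_method = "pmf", rtol = 1e-10, atol = 1e-12) {
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  bw <- beta + omega
  if (bw <= 0) stop("requires beta + omega > 0")
  pw <- params$p_omega
  mu <- sum((0:dspec$kmax) * dspec$pmf)
  fp <- function(s) pgf_deriv(dspec, s, order = 1, method = pgf_method)
  rhs <- function(t, w, p) {
    xi <- w[1]; theta <- w[2]
    e <- exp(bw * xi)
    psi_xi <- pw + (1 - pw) / e
    dxi <- 1 + (gamma / bw) * (1 - e) - e * fp(psi_xi) / mu
    dtheta <- beta * fp(theta) / mu - (beta + gamma + omega) * theta +
      gamma + omega
    list(c(dxi, dtheta))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(c(0, 1), times, rhs, NULL, rtol = rtol, atol = atol)
  xi <- sol[, 2]
  list(time = times, xi = xi, theta = sol[, 3],
       psi_of_xi = pw + (1 - pw) * exp(-bw * xi))
}

#' Infective fraction in transformed time
#'
#' Solves `dy~/dt = -(gamma / rho~_E(t)) y~ + beta e^{-(beta+omega)t}
#' f'(psi(t))` with `y~(0) = eps` (the initially infective fraction), using
#' the closed forms for `rho~_E`. The inhomogeneous term is the incidence
#' `-dx~/dt`. The grid is truncated (with a warning) where it extends past
#' the hitting time `tau~` at which the infective stub fraction vanishes.
#'
#' @inheritParams closed_form_tilde
#' @param t_grid increasing time grid starting at values `>= 0`.
#' @return a data frame with columns `time` and `y`.
#' @export
infective_fraction_tilde <- function(params, dspec, t_grid,
                                     pgf_method = "pmf",
                                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(all(diff(t_grid) > 0), t_grid[1] >= 0)
  cf <- closed_form_tilde(params, dspec, t_grid, pgf_method)
  ok <- cf$yE > 0
  if (!all(ok)) {
    warning("grid extends past the hitting time tau~; truncating")
    t_grid <- t_grid[ok]
  }
  beta <- params$beta; gamma <- params$gamma
  bw <- beta + params$omega
  rhs <- function(t, w, p) {
    c1 <- closed_form_tilde(params, dspec, t, pgf_method)
    rho <- c1$yE / c1$etaE
    list(-gamma / rho * w[1] + beta * exp(-bw * t) *
           pgf_deriv(dspec, c1$psi, order = 1, method = pgf_method))
  }
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  sol <- deSolve::ode(dspec$eps_total, times, rhs, NULL,
                      rtol = rtol, atol = atol)
  keep <- sol[, 1] %in% t_grid
  data.frame(time = sol[keep, 1], y = sol[keep, 2])
}
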