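# Density-dependent-process fluctuation machinery for the effective-degree
# chain. State ordering convention used by everything in this file (and by
# the covariance matrices returned from it): (x_0..x_M, y_0..y_M, z_E).

#' Enumerate the jump vectors and intensity functions
#'
#' Builds the full list of jumps of the effective-degree chain: infection of
#' a type-j susceptible by a type-i infective, pairing of two infective
#' stubs, warning (dropping) of a type-j susceptible, pairing of an
#' infective stub with a recovered stub, and recovery. Each jump is a row of
#' the matrix `L` over the `(x, y, z_E)` coordinates; `rates(w)` returns the
#' corresponding intensity vector at state fractions `w` (real-time variant,
#' with total stub fraction `eta_E` in the denominators) or the
#' time-transformed variant (denominator `y_E`, recovery intensity
#' multiplied by `eta_E/y_E`).
#'
#' @param M maximum effective degree.
#' @param params an [epidemic_params()].
#' @param variant `"real"` or `"transformed"`.
#' @return a list with `L` (njump x (2M+3) matrix), `rates(w)`, and the
#'   bookkeeping vectors `type`, `i`, `j`.
#' @export
jump_model <- function(M, params, variant = c("real", "transformed")) {
  variant <- match.arg(variant)
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  n <- 2 * M + 3
  xi <- function(i) i + 1          # x_i column
  yi <- function(i) M + 2 + i      # y_i column
  zi <- n
  ii <- rep(1:M, each = M); jj <- rep(1:M, times = M)
  rows <- list(); type <- integer(0); iv <- integer(0); jv <- integer(0)
  add <- function(l, tp, i, j) {
    rows[[length(rows) + 1]] <<- l
    type[[length(type) + 1]] <<- tp
    iv[[length(iv) + 1]] <<- i
    jv[[length(jv) + 1]] <<- j
  }
  for (k in seq_along(ii)) {  # pair (i, j), i infective actor, j partner
    i <- ii[k]; j <- jj[k]
    l1 <- numeric(n)  # infection of type-j susceptible
    l1[yi(i)] <- l1[yi(i)] - 1; l1[yi(i - 1)] <- l1[yi(i - 1)] + 1
    l1[xi(j)] <- l1[xi(j)] - 1; l1[yi(j - 1)] <- l1[yi(j - 1)] + 1
    add(l1, 1L, i, j)
    l2 <- numeric(n)  # edge between two infective stubs
    l2[yi(i)] <- l2[yi(i)] - 1; l2[yi(i - 1)] <- l2[yi(i - 1)] + 1
    l2[yi(j)] <- l2[yi(j)] - 1; l2[yi(j - 1)] <- l2[yi(j - 1)] + 1
    add(l2, 2L, i, j)
    l3 <- numeric(n)  # warning: susceptible drops the stub
    l3[yi(i)] <- l3[yi(i)] - 1; l3[yi(i - 1)] <- l3[yi(i - 1)] + 1
    l3[xi(j)] <- l3[xi(j)] - 1; l3[xi(j - 1)] <- l3[xi(j - 1)] + 1
    add(l3, 3L, i, j)
  }
  for (i in 1:M) {  # infective stub pairs with a recovered stub
    l4 <- numeric(n)
    l4[yi(i)] <- -1; l4[yi(i - 1)] <- l4[yi(i - 1)] + 1; l4[zi] <- -1
    add(l4, 4L, i, NA_integer_)
  }
  for (i in 0:M) {  # recovery of a type-i infective
    l5 <- numeric(n)
    l5[yi(i)] <- l5[yi(i)] - 1; l5[zi] <- l5[zi] + i
    add(l5, 5L, i, NA_integer_)
  }
  L <- do.call(rbind, rows)
  type <- unlist(type); iv <- unlist(iv); jv <- unlist(jv)
  rates <- function(w) {
    x <- w[1:(M + 1)]; y <- w[(M + 2):(2 * M + 2)]; z <- w[2 * M + 3]
    deg <- 0:M
    yE <- sum(deg * y); etaE <- sum(deg * x) + yE + z
    den <- if (variant == "real") etaE else yE
    r <- numeric(length(type))
    wi <- iv * y[iv + 1]
    r[type == 1L] <- beta * (wi * jv * x[jv + 1])[type == 1L] / den
    r[type == 2L] <- (beta + omega) * (wi * jv * y[jv + 1])[type == 2L] / den
    r[type == 3L] <- omega * (wi * jv * x[jv + 1])[type == 3L] / den
    r[type == 4L] <- (beta + omega) * (iv * y[iv + 1])[type == 4L] * z / den
    r5 <- gamma * y[iv[type == 5L] + 1]
    if (variant == "transformed") r5 <- r5 * etaE / yE
    r[type == 5L] <- r5
    r
  }
  list(L = L, rates = rates, type = type, i = iv, j = jv, M = M,
       variant = variant)
}

#' Drift of the effective-degree chain
#'
#' Closed-form drift `F(w)` (the right-hand side of the deterministic limit)
#' at state fractions `w = (x, y, z_E)`, for the real-time or
#' time-transformed variant. `method = "jumps"` instead sums
#' `l * beta_l(w)` over the enumerated jump list, which is the defining
#' expression; the two must agree to machine precision.
#'
#' @param w numeric state vector of length `2M+3`.
#' @param params an [epidemic_params()].
#' @param variant `"real"` or `"transformed"`.
#' @param method `"closed"` or `"jumps"`.
#' @export
drift <- function(w, params, variant = c("real", "transformed"),
                  method = c("closed", "jumps")) {
  variant <- match.arg(variant); method <- match.arg(method)
  M <- (length(w) - 3L) / 2L
  if (method == "jumps") {
    jm <- jump_model(M, params, variant)
    return(drop(jm$rates(w) %*% jm$L))
  }
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  i <- 0:M
  x <- w[1:(M + 1)]; y <- w[(M + 2):(2 * M + 2)]; z <- w[2 * M + 3]
  yE <- sum(i * y); etaE <- sum(i * x) + yE + z
  up_x <- shift_down_weighted(x); up_y <- shift_down_weighted(y)
  A <- -beta * i * x + omega * (up_x - i * x)
  B <- up_y - i * y
  if (variant == "real") {
    rho <- if (etaE > 0) yE / etaE else 0
    dx <- rho * A
    dy <- (beta + omega) * B * (1 + rho) + beta * rho * up_x - gamma * y
    dz <- gamma * yE - (beta + omega) * rho * z
  } else {
    if (yE <= 0) stop("transformed drift is singular at y_E = 0")
    rho <- yE / etaE
    dx <- A
    dy <- ((beta + omega) * B - gamma * y) / rho + (beta + omega) * B +
      beta * up_x
    dz <- gamma * etaE - (beta + omega) * z
  }
  c(dx, dy, dz)
}

#' Local diffusion matrix of the fluctuation process
#'
#' `G(w) = sum_l l^T l beta_l(w)` over the enumerated jumps: the local
#' covariance of the compensated jump process, which drives the Gaussian
#' fluctuations about the deterministic limit. Symmetric positive
#' semidefinite by construction.
#'
#' @inheritParams drift
#' @export
diffusion_G <- function(w, params, variant = c("real", "transformed")) {
  variant <- match.arg(variant)
  M <- (length(w) - 3L) / 2L
  jm <- jump_model(M, params, variant)
  r <- jm$rates(w)
  crossprod(jm$L, jm$L * r)
}

#' Jacobian of the drift
#'
#' Analytic matrix of first partial derivatives `[d F_i / d w_j]` of the
#' drift, in the `(x, y, z_E)` ordering. This is the coefficient matrix of
#' the linear drift of the limiting Gaussian process and enters the
#' covariance ODE.
#'
#' @inheritParams drift
#' @export
jacobian_dF <- function(w, params, variant = c("real", "transformed")) {
  variant <- match.arg(variant)
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  bw <- beta + omega
  M <- (length(w) - 3L) / 2L
  n <- 2 * M + 3
  i <- 0:M
  x <- w[1:(M + 1)]; y <- w[(M + 2):(2 * M + 2)]; z <- w[n]
  yE <- sum(i * y); etaE <- sum(i * x) + yE + z
  rho <- yE / etaE
  up_x <- shift_down_weighted(x); up_y <- shift_down_weighted(y)
  A <- -bw * i * x + omega * up_x   # == -beta i x + omega(-ix + (i+1)x_{i+1})
  B <- up_y - i * y
  # gradient of rho = yE/etaE over (x, y, z)
  grho <- c(-i * rho / etaE, i * (1 - rho) / etaE, -rho / etaE)
  # banded helper matrices over a degree block
  DA <- matrix(0, M + 1, M + 1)   # dA_i/dx_j
  S <- matrix(0, M + 1, M + 1)    # (i+1) delta_{j,i+1}
  Dif <- matrix(0, M + 1, M + 1)  # dB_i/dy_j
  for (r in 0:M) {
    DA[r + 1, r + 1] <- -bw * r
    Dif[r + 1, r + 1] <- -r
    if (r < M) {
      DA[r + 1, r + 2] <- omega * (r + 1)
      S[r + 1, r + 2] <- r + 1
      Dif[r + 1, r + 2] <- r + 1
    }
  }
  J <- matrix(0, n, n)
  ix <- 1:(M + 1); iy <- (M + 2):(2 * M + 2); iz <- n
  if (variant == "real") {
    K <- bw * B + beta * up_x
    J[ix, ix] <- rho * DA
    J[ix, ] <- J[ix, ] + outer(A, grho)
    J[iy, ix] <- beta * rho * S
    J[iy, iy] <- bw * (1 + rho) * Dif - gamma * diag(M + 1)
    J[iy, ] <- J[iy, ] + outer(K, grho)
    J[iz, iy] <- gamma * i
    J[iz, iz] <- -bw * rho
    J[iz, ] <- J[iz, ] - bw * z * grho
  } else {
    if (yE <= 0) stop("transformed Jacobian is singular at y_E = 0")
    C <- bw * B - gamma * y
    J[ix, ix] <- DA
    J[iy, ix] <- beta * S
    J[iy, iy] <- bw * (1 + 1 / rho) * Dif - (gamma / rho) * diag(M + 1)
    J[iy, ] <- J[iy, ] + outer(C, -grho / rho^2)
    J[iz, ix] <- gamma * i
    J[iz, iy] <- gamma * i
    J[iz, iz] <- gamma - bw
  }
  J
}

#' Initial covariance of the state fractions on an NSW graph
#'
#' On an NSW graph the iid degrees make the initial effective-degree counts
#' random: with a fraction `eps` of individuals initially infective (chosen
#' uniformly), the susceptible block of the scaled initial covariance is the
#' multinomial form `p_i(1-p_i)(1-eps)` on the diagonal and
#' `-p_i p_j (1-eps)` off it, the infective block is the same with `eps`,
#' and all other entries vanish.
#'
#' @param dist a [degree_dist()].
#' @param eps initially-infective fraction in `[0, 1)`.
#' @return a `(2M+3) x (2M+3)` covariance matrix in the standard ordering.
#' @export
nsw_initial_covariance <- function(dist, eps) {
  stopifnot(eps >= 0, eps < 1)
  p <- dist$pmf
  M <- dist$kmax
  n <- 2 * M + 3
  block <- -outer(p, p)
  diag(block) <- p * (1 - p)
  S <- matrix(0, n, n)
  S[1:(M + 1), 1:(M + 1)] <- (1 - eps) * block
  S[(M + 2):(2 * M + 2), (M + 2):(2 * M + 2)] <- eps * block
  S
}

#' Solve the fluctuation covariance ODE along the deterministic limit
#'
#' Jointly integrates the deterministic state `w(t)` and the covariance
#' `Sigma(t)` of the Gaussian fluctuation process, which satisfies
#' `dSigma/dt = G(w) + dF(w) Sigma + Sigma dF(w)^T` with `Sigma(0) = Sigma0`
#' (zero for MR initial conditions; [nsw_initial_covariance()] for NSW). In
#' the transformed variant the integration stops by event detection when the
#' infective stub fraction reaches `stop_at`.
#'
#' @param params an [epidemic_params()].
#' @param dspec a [deficit_dist()] with `eps_E > 0`.
#' @param Sigma0 initial covariance (`NULL` for zero).
#' @param t_end end time (real variant).
#' @param variant `"real"` or `"transformed"`.
#' @param stop_at event level for `y_E` (transformed variant; must be > 0).
#' @param n_out,rtol,atol output grid and tolerances.
#' @return an object of class `cov_solution`: `time`, `w` (matrix of states),
#'   `Sigma` (list of matrices), `tau_delta` (transformed variant),
#'   `prevalence_var` (variance of the infective fraction) and
#'   `susceptible_var`.
#' @export
solve_covariance <- function(params, dspec, Sigma0 = NULL, t_end = NULL,
                             variant = c("real", "transformed"),
                             stop_at = NULL, n_out = 101,
                             rtol = 1e-7, atol = 1e-9) {
  variant <- match.arg(variant)
  if (dspec$eps_E <= 0) stop("requires eps_E > 0")
  M <- dspec$kmax
  n <- 2 * M + 3
  w0 <- ode_initial_state(dspec)
  if (is.null(Sigma0)) Sigma0 <- matrix(0, n, n)
  stopifnot(nrow(Sigma0) == n, ncol(Sigma0) == n,
            max(abs(Sigma0 - t(Sigma0))) < 1e-9)
  jm <- jump_model(M, params, variant)
  L <- jm$L
  lower <- which(lower.tri(matrix(0, n, n), diag = TRUE))
  tri_expand <- function(v) {
    S <- matrix(0, n, n)
    S[lower] <- v
    S <- S + t(S)
    diag(S) <- diag(S) / 2
    S
  }
  rhs <- function(t, state, p) {
    w <- state[1:n]
    S <- tri_expand(state[-(1:n)])
    Fw <- drift(w, params, variant)
    J <- jacobian_dF(w, params, variant)
    r <- jm$rates(w)
    G <- crossprod(L, L * r)
    dS <- G + J %*% S + S %*% t(J)
    list(c(Fw, dS[lower]))
  }
  state0 <- c(w0, Sigma0[lower])
  if (variant == "real") {
    stopifnot(!is.null(t_end))
    times <- seq(0, t_end, length.out = n_out)
    sol <- deSolve::ode(state0, times, rhs, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    tau_delta <- NA_real_
  } else {
    stopifnot(!is.null(stop_at), stop_at > 0, stop_at < dspec$eps_E)
    deg <- 0:M
    rootfun <- function(t, state, p) {
      sum(deg * state[(M + 2):(2 * M + 2)]) - stop_at
    }
    t_cap <- guess_tau_cap(params, dspec, stop_at)
    times <- seq(0, t_cap, length.out = n_out)
    sol <- deSolve::lsodar(state0, times, rhs, NULL, rtol = rtol, atol = atol,
                           rootfunc = rootfun)
    troot <- attr(sol, "troot")
    tau_delta <- if (length(troot) > 0) troot[1] else NA_real_
  }
  tm <- sol[, 1]
  W <- sol[, 2:(n + 1), drop = FALSE]
  Sig <- lapply(seq_along(tm), function(k) tri_expand(sol[k, -(1:(n + 1))]))
  iy <- (M + 2):(2 * M + 2)
  ixs <- 1:(M + 1)
  prev_var <- vapply(Sig, function(S) sum(S[iy, iy]), numeric(1))
  susc_var <- vapply(Sig, function(S) sum(S[ixs, ixs]), numeric(1))
  structure(list(time = tm, w = W, Sigma = Sig, tau_delta = tau_delta,
                 prevalence_var = prev_var, susceptible_var = susc_var,
                 M = M, variant = variant),
            class = "cov_solution")
}

#' @export
print.cov_solution <- function(x, ...) {
  cat(sprintf(
    "Fluctuation covariance solution (%s time), M = %d, %d time points\n",
    x$variant, x$M, length(x$time)))
  invisible(x)
}

#' Project the covariance onto the hitting hyperplane
#'
#' At the hitting time of `y_E = delta` the fluctuation of the crossing time
#' feeds back into the state; the corrected covariance of the state at the
#' hitting time is `B Sigma B^T` with the oblique projector
#' `B = I - (F(w) outer grad phi) / (grad phi . F(w))`, `phi(w) = y_E`.
#' Requires the transversality condition `grad phi . F(w) < 0`.
#'
#' @param w state at the hitting time (transformed variant).
#' @param Sigma covariance at the hitting time.
#' @param params an [epidemic_params()].
#' @return the projected covariance matrix.
#' @export
hitting_projection <- function(w, Sigma, params) {
  M <- (length(w) - 3L) / 2L
  Fw <- drift(w, params, "transformed")
  grad <- c(rep(0, M + 1), 0:M, 0)
  denom <- sum(grad * Fw)
  if (denom >= 0) stop("crossing condition grad(phi) . F < 0 fails")
  B <- diag(length(w)) - outer(Fw, grad) / denom
  B %*% Sigma %*% t(B)
}

#' Final-size variance via the covariance-ODE route
#'
#' Independent numerical route to the MR final-size variance: integrate the
#' transformed-time covariance ODE to the hitting level `y_E = delta`, apply
#' the hitting-time projection, contract with the susceptible-count weights
#' `(1, 0, 0)`, and extrapolate `delta` to zero (the ODE itself is singular
#' at the extinction time, so small positive levels are extrapolated with a
#' quadratic fit).
#'
#' @param params an [epidemic_params()].
#' @param dspec a [deficit_dist()] with `eps_E > 0`.
#' @param deltas decreasing positive hitting levels.
#' @param ... passed to [solve_covariance()].
#' @return list with `sigma2` (extrapolated), `by_delta`.
#' @export
sigma2_mr_ode <- function(params, dspec, deltas = c(0.05, 0.02, 0.01), ...) {
  M <- dspec$kmax
  vals <- vapply(deltas, function(d) {
    cs <- solve_covariance(params, dspec, variant = "transformed",
                           stop_at = d, ...)
    if (is.na(cs$tau_delta)) stop("hitting level not reached")
    k <- length(cs$time)
    P <- hitting_projection(cs$w[k, ], cs$Sigma[[k]], params)
    wts <- c(rep(1, M + 1), rep(0, M + 1), 0)
    drop(wts %*% P %*% wts)
  }, numeric(1))
  sigma2 <- if (length(deltas) >= 3) {
    fit <- stats::lm(vals ~ poly(deltas, 2, raw = TRUE))
    unname(stats::predict(fit, data.frame(deltas = 0)))
  } else {
    vals[length(vals)]
  }
  list(sigma2 = sigma2, by_delta = data.frame(delta = deltas, sigma2 = vals))
}
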