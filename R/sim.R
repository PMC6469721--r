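#' Molloy-Reed degree counts by largest-remainder rounding
#'
#' Converts a target degree pmf into a deterministic degree sequence for a
#' population of size `N`: counts are `floor(N * p_k)` with the remaining
#' individuals assigned to the degrees with the largest fractional parts.
#' Used both for building MR networks and for apportioning a fixed number of
#' initial infectives across degrees in the same proportions as the
#' population.
#'
#' @param pmf probability vector over degrees `0:kmax`.
#' @param N total count to distribute.
#' @return integer vector of counts summing to `N`.
#' @export
largest_remainder_counts <- function(pmf, N) {
  tgt <- N * pmf / sum(pmf)
  counts <- floor(tgt)
  short <- N - sum(counts)
  if (short > 0) {
    ord <- order(tgt - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

effdeg_initial_state <- function(dist, N, i0, mode = c("MR", "NSW")) {
  mode <- match.arg(mode)
  stopifnot(i0 >= 1, i0 < N)
  if (mode == "MR") {
    n_by_deg <- largest_remainder_counts(dist$pmf, N)
    y0 <- largest_remainder_counts(dist$pmf, i0)
    y0 <- pmin(y0, n_by_deg)
    # if the cap bit, place the shortfall wherever capacity remains
    short <- i0 - sum(y0)
    while (short > 0) {
      cap <- which(n_by_deg - y0 > 0)
      take <- cap[which.max((n_by_deg - y0)[cap])]
      y0[take] <- y0[take] + 1L
      short <- short - 1L
    }
    list(x0 = n_by_deg - y0, y0 = y0)
  } else {
    deg <- sample(0:dist$kmax, N, replace = TRUE, prob = dist$pmf)
    inf <- sample.int(N, i0)
    y0 <- tabulate(deg[inf] + 1L, nbins = dist$kmax + 1L)
    x0 <- tabulate(deg[-inf] + 1L, nbins = dist$kmax + 1L)
    list(x0 = as.integer(x0), y0 = as.integer(y0))
  }
}

#' Simulate one epidemic via the effective-degree Markov chain
#'
#' Exact Gillespie simulation of the continuous-time Markov chain in which
#' the network is constructed while the epidemic spreads: an infective's
#' unpaired stubs fire at rate `beta + omega` each, the activated stub pairs
#' with a uniformly chosen other unpaired stub (self-pairings included), the
#' event is a transmission with probability `beta/(beta+omega)` and a warning
#' otherwise, and infectives recover at rate `gamma`. A warned susceptible
#' drops the stub; warned/contacted infectives and recovered individuals just
#' form an edge. When the total number of unpaired stubs is odd, the final
#' left-over stub can never pair.
#'
#' @param params an [epidemic_params()].
#' @param dist a [degree_dist()]; the simulation draws from its (truncated)
#'   pmf.
#' @param N population size.
#' @param i0 number of initial infectives.
#' @param mode `"MR"` (deterministic degree counts, initial infectives
#'   apportioned proportionally across degrees) or `"NSW"` (iid degrees,
#'   initial infectives uniform).
#' @param record if `TRUE`, return the event-time trajectory of the numbers
#'   of infectives, susceptibles and infective stubs.
#' @return a list with `final_size` (ever-infected count, initial infectives
#'   included), `extinction_time`, `x_final` (susceptibles by effective
#'   degree) and optionally `trajectory`.
#' @export
simulate_epidemic <- function(params, dist, N, i0, mode = c("MR", "NSW"),
                              record = FALSE) {
  stopifnot(inherits(params, "epidemic_params"), inherits(dist, "degree_dist"),
            N >= 2)
  mode <- match.arg(mode)
  init <- effdeg_initial_state(dist, N, i0, mode)
  out <- sim_effdeg_cpp(init$x0, init$y0, params$beta, params$gamma,
                        params$omega, record)
  out$mode <- mode
  out
}

#' Ensemble of effective-degree simulations
#'
#' Runs `n_reps` independent epidemics and returns the per-replicate final
#' size and extinction time. For `mode = "NSW"` each replicate redraws the
#' iid degree sequence; for `mode = "MR"` the deterministic initial counts
#' are reused.
#'
#' @inheritParams simulate_epidemic
#' @param n_reps number of replicates.
#' @return a data frame with columns `final_size` and `extinction_time`.
#' @export
simulate_ensemble <- function(params, dist, N, i0, n_reps,
                              mode = c("MR", "NSW")) {
  mode <- match.arg(mode)
  if (mode == "MR") {
    init <- effdeg_initial_state(dist, N, i0, "MR")
    m <- sim_effdeg_ensemble_cpp(dist$pmf, N, i0, FALSE, init$x0, init$y0,
                                 params$beta, params$gamma, params$omega,
                                 n_reps)
  } else {
    m <- sim_effdeg_ensemble_cpp(dist$pmf, N, i0, TRUE, integer(0), integer(0),
                                 params$beta, params$gamma, params$omega,
                                 n_reps)
  }
  data.frame(final_size = m[, 1], extinction_time = m[, 2])
}

#' Ensemble of effective-degree simulations from explicit initial counts
#'
#' Lower-level variant of [simulate_ensemble()] taking the initial
#' susceptible/infective counts by effective degree directly; useful for
#' tiny hand-built configurations (and for comparison against
#' [exact_final_size_pmf()], which consumes the same state).
#'
#' @inheritParams exact_final_size_pmf
#' @param n_reps number of replicates.
#' @return a data frame with columns `final_size` and `extinction_time`.
#' @export
simulate_ensemble_counts <- function(params, x0, y0, n_reps) {
  stopifnot(length(x0) == length(y0), all(x0 >= 0), all(y0 >= 0))
  m <- sim_effdeg_ensemble_cpp(numeric(0), 0L, 0L, FALSE,
                               as.integer(x0), as.integer(y0),
                               params$beta, params$gamma, params$omega,
                               n_reps)
  data.frame(final_size = m[, 1], extinction_time = m[, 2])
}

#' Simulate on an explicitly constructed configuration-model graph
#'
#' Reference backend: all stubs are paired uniformly at random up front
#' (retaining self-loops and multi-edges; an odd left-over stub is ignored)
#' and the epidemic then runs on the realized multigraph, with each
#' susceptible-infective edge transmitting at rate `beta` and being dropped
#' by the susceptible at rate `omega`, and infectives recovering at rate
#' `gamma`. Distributionally equivalent to [simulate_epidemic()].
#'
#' @param params an [epidemic_params()].
#' @param degree_sequence integer vector of degrees, one per individual.
#' @param init_infective indices (1-based) of the initially infective
#'   individuals.
#' @return list with `final_size` and `extinction_time`.
#' @export
simulate_graph_epidemic <- function(params, degree_sequence, init_infective) {
  stopifnot(all(degree_sequence >= 0), length(init_infective) >= 1)
  sim_graph_cpp(as.integer(degree_sequence),
                as.integer(init_infective) - 1L,
                params$beta, params$gamma, params$omega)
}

#' Ensemble of explicit-graph simulations
#'
#' @inheritParams simulate_ensemble
#' @param degree_sequence for `mode = "MR"`, the fixed degree sequence
#'   (defaults to largest-remainder counts from `dist`).
#' @export
simulate_graph_ensemble <- function(params, dist, N, i0, n_reps,
                                    mode = c("MR", "NSW"),
                                    degree_sequence = NULL) {
  mode <- match.arg(mode)
  if (is.null(degree_sequence)) {
    counts <- largest_remainder_counts(dist$pmf, N)
    degree_sequence <- rep(0:dist$kmax, counts)
  }
  m <- sim_graph_ensemble_cpp(dist$pmf, N, i0, mode == "NSW",
                              as.integer(degree_sequence),
                              params$beta, params$gamma, params$omega, n_reps)
  data.frame(final_size = m[, 1], extinction_time = m[, 2])
}

#' Exact final-size distribution by state-space enumeration
#'
#' Brute-force oracle for tiny populations: enumerates the reachable states
#' of the effective-degree Markov chain (including the exact self-pairing
#' corrections and the rule that a lone remaining stub never pairs) and
#' propagates probability through the embedded jump chain. Every transition
#' strictly decreases (total unpaired stubs, number of infectives) in
#' lexicographic order, so the state graph is acyclic and absorption
#' probabilities follow by a single forward sweep; a state is absorbing for
#' final-size purposes as soon as no infective stub can ever pair again.
#'
#' @param params an [epidemic_params()].
#' @param x0,y0 integer vectors: initial susceptible/infective counts by
#'   effective degree `0..M`.
#' @param max_states guard on the enumeration size.
#' @return a data frame with columns `final_size` and `prob`.
#' @export
exact_final_size_pmf <- function(params, x0, y0, max_states = 1e5) {
  beta <- params$beta; gamma <- params$gamma; omega <- params$omega
  M <- length(x0) - 1L
  stopifnot(length(y0) == M + 1L)
  nstub0 <- sum((0:M) * (x0 + y0))
  if (nstub0 > 10) stop("total stubs must be <= 10 for exact enumeration")
  Npop <- sum(x0) + sum(y0)
  pmf <- numeric(Npop + 1)  # index = final size + 1

  key <- function(st) paste(st, collapse = ",")
  # levels[[stubs]][[ysum]] : environment of key -> list(state, prob)
  n_states <- 0L
  levels <- list()
  add_mass <- function(st, pr, lv) {
    ks <- as.character(lv[1]); ky <- as.character(lv[2])
    if (is.null(levels[[ks]])) levels[[ks]] <<- list()
    if (is.null(levels[[ks]][[ky]])) levels[[ks]][[ky]] <<- new.env(parent = emptyenv())
    e <- levels[[ks]][[ky]]
    k <- key(st)
    if (is.null(e[[k]])) {
      e[[k]] <- list(state = st, prob = pr)
      n_states <<- n_states + 1L
      if (n_states > max_states) stop("state space too large")
    } else {
      e[[k]]$prob <- e[[k]]$prob + pr
    }
  }
  st0 <- c(as.integer(x0), as.integer(y0), 0L)
  add_mass(st0, 1, c(nstub0, sum(y0)))

  xi <- 1:(M + 1); yi <- (M + 2):(2 * M + 2); zi <- 2 * M + 3
  idx <- 0:M
  for (stubs in seq(nstub0, 0)) {
    ks <- as.character(stubs)
    if (is.null(levels[[ks]])) next
    for (ysum in seq(Npop, 0)) {
      ky <- as.character(ysum)
      e <- levels[[ks]][[ky]]
      if (is.null(e)) next
      for (k in ls(e)) {
        rec <- e[[k]]
        st <- rec$state; pr <- rec$prob
        x <- st[xi]; y <- st[yi]; z <- st[zi]
        ny <- sum(idx * y); nx <- sum(idx * x)
        tot <- nx + ny + z
        if (ny == 0 || tot < 2) {
          fs <- Npop - sum(x)
          pmf[fs + 1] <- pmf[fs + 1] + pr
          next
        }
        # build transition list: (rate, new state)
        rates <- numeric(0); news <- list()
        push <- function(rate, st2) {
          rates[[length(rates) + 1]] <<- rate
          news[[length(news) + 1]] <<- st2
        }
        den <- tot - 1
        for (i in which(y[-1] > 0)) {  # i = effective degree >= 1
          wi <- i * y[i + 1]
          # susceptible partners
          for (j in which(x[-1] > 0)) {
            r_pair <- wi * j * x[j + 1] / den
            if (beta > 0) {  # infection of type-j susceptible
              st2 <- st
              st2[yi[i + 1]] <- st2[yi[i + 1]] - 1L
              st2[yi[i]] <- st2[yi[i]] + 1L
              st2[xi[j + 1]] <- st2[xi[j + 1]] - 1L
              st2[yi[j]] <- st2[yi[j]] + 1L
              push(beta * r_pair, st2)
            }
            if (omega > 0) {  # warning: susceptible drops the stub
              st2 <- st
              st2[yi[i + 1]] <- st2[yi[i + 1]] - 1L
              st2[yi[i]] <- st2[yi[i]] + 1L
              st2[xi[j + 1]] <- st2[xi[j + 1]] - 1L
              st2[xi[j]] <- st2[xi[j]] + 1L
              push(omega * r_pair, st2)
            }
          }
          # other infectives' stubs (edge formed)
          for (j in which(y[-1] > 0)) {
            wgt <- j * y[j + 1] - if (j == i) i else 0
            if (wgt > 0) {
              st2 <- st
              st2[yi[i + 1]] <- st2[yi[i + 1]] - 1L
              st2[yi[i]] <- st2[yi[i]] + 1L
              st2[yi[j + 1]] <- st2[yi[j + 1]] - 1L
              st2[yi[j]] <- st2[yi[j]] + 1L
              push((beta + omega) * wi * wgt / den, st2)
            }
          }
          # self-pairing: two of the actor's own stubs
          if (i >= 2) {
            st2 <- st
            st2[yi[i + 1]] <- st2[yi[i + 1]] - 1L
            st2[yi[i - 1]] <- st2[yi[i - 1]] + 1L
            push((beta + omega) * i * (i - 1) * y[i + 1] / den, st2)
          }
          # recovered stubs (edge formed)
          if (z > 0) {
            st2 <- st
            st2[yi[i + 1]] <- st2[yi[i + 1]] - 1L
            st2[yi[i]] <- st2[yi[i]] + 1L
            st2[zi] <- st2[zi] - 1L
            push((beta + omega) * wi * z / den, st2)
          }
        }
        # recoveries
        if (gamma > 0) {
          for (i in which(y > 0) - 1L) {
            st2 <- st
            st2[yi[i + 1]] <- st2[yi[i + 1]] - 1L
            st2[zi] <- st2[zi] + i
            push(gamma * y[i + 1], st2)
          }
        }
        tot_rate <- sum(unlist(rates))
        if (tot_rate <= 0) {  # stuck (gamma = 0, nothing can pair)
          fs <- Npop - sum(x)
          pmf[fs + 1] <- pmf[fs + 1] + pr
          next
        }
        for (m in seq_along(news)) {
          st2 <- news[[m]]
          y2 <- st2[yi]
          stubs2 <- sum(idx * st2[xi]) + sum(idx * y2) + st2[zi]
          add_mass(st2, pr * rates[[m]] / tot_rate, c(stubs2, sum(y2)))
        }
      }
      levels[[ks]][[ky]] <- NULL
    }
  }
  keep <- pmf > 0
  data.frame(final_size = which(keep) - 1L, prob = pmf[keep])
}

#' Estimate the major-outbreak probability by simulation
#'
#' Classifies replicate epidemics as major when the final size reaches
#' `threshold_frac * N` and reports the estimated probability with an exact
#' binomial 95% confidence interval, together with the mean and standard
#' deviation of the final size among major outbreaks (t- and chi-squared
#' based confidence intervals; sd interval endpoints are the square roots of
#' the variance interval endpoints).
#'
#' @inheritParams simulate_ensemble
#' @param threshold_frac major-outbreak threshold as a fraction of `N`
#'   (default 0.15).
#' @param backend `"effdeg"` or `"graph"`.
#' @return a list with `p_hat`, `p_ci`, `n_major`, `major_mean`, `major_mean_ci`,
#'   `major_sd`, `major_sd_ci`, and the replicate table `runs`.
#' @export
estimate_major_outbreak <- function(params, dist, N, i0, n_reps,
                                    threshold_frac = 0.15,
                                    mode = c("NSW", "MR"),
                                    backend = c("effdeg", "graph")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  runs <- if (backend == "effdeg") {
    simulate_ensemble(params, dist, N, i0, n_reps, mode)
  } else {
    simulate_graph_ensemble(params, dist, N, i0, n_reps, mode)
  }
  major <- runs$final_size >= threshold_frac * N
  n_major <- sum(major)
  p_hat <- n_major / n_reps
  p_ci <- as.numeric(stats::binom.test(n_major, n_reps)$conf.int)
  out <- list(p_hat = p_hat, p_ci = p_ci, n_major = n_major,
              n_reps = n_reps, threshold = threshold_frac * N, runs = runs)
  if (n_major >= 2) {
    fs <- runs$final_size[major]
    m <- mean(fs); v <- stats::var(fs); n <- length(fs)
    tq <- stats::qt(0.975, n - 1)
    out$major_mean <- m
    out$major_mean_ci <- m + c(-1, 1) * tq * sqrt(v / n)
    out$major_sd <- sqrt(v)
    v_ci <- (n - 1) * v / stats::qchisq(c(0.975, 0.025), n - 1)
    out$major_sd_ci <- sqrt(v_ci)
  } else {
    out$major_mean <- NA_real_
    out$major_sd <- NA_real_
  }
  out
}
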