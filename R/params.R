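#' Epidemic rate parameters
#'
#' Bundles the per-edge infection rate `beta`, the recovery rate `gamma` and
#' the per-edge dropping (warning) rate `omega`. The derived quantity
#' `p_omega = omega / (beta + omega)` is the probability that a given
#' susceptible-infective edge is dropped before transmitting, conditional on
#' one of the two happening.
#'
#' @param beta infection rate per susceptible-infective edge (>= 0).
#' @param gamma recovery rate (>= 0).
#' @param omega dropping rate per susceptible-infective edge (>= 0).
#' @return an object of class `epidemic_params`.
#' @export
epidemic_params <- function(beta, gamma, omega = 0) {
  stopifnot(is.finite(beta), is.finite(gamma), is.finite(omega),
            beta >= 0, gamma >= 0, omega >= 0)
  if (beta + gamma + omega <= 0) stop("need beta + gamma + omega > 0")
  p_omega <- if (beta + omega > 0) omega / (beta + omega) else 0
  structure(list(beta = beta, gamma = gamma, omega = omega, p_omega = p_omega),
            class = "epidemic_params")
}

#' @export
print.epidemic_params <- function(x, ...) {
  cat(sprintf(
    "Epidemic rates: beta = %g (infection), gamma = %g (recovery), omega = %g (dropping)\n",
    x$beta, x$gamma, x$omega))
  cat(sprintf("  p_omega = omega/(beta+omega) = %.6g\n", x$p_omega))
  invisible(x)
}

#' Modified model with increased recovery instead of dropping
#'
#' Returns the parameter set of the companion model `E(0, gamma + omega)`:
#' no dropping, recovery rate increased by the dropping rate. It shares the
#' reproduction number, Malthusian parameter, deterministic susceptible
#' process and final size with the dropping model, but not its fluctuations
#' or outbreak probability.
#'
#' @param params an `epidemic_params`.
#' @export
modified_params <- function(params) {
  stopifnot(inherits(params, "epidemic_params"))
  epidemic_params(params$beta, params$gamma + params$omega, 0)
}
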