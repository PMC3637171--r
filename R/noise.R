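# Multiplicative Ornstein-Uhlenbeck extrinsic noise on selected rate
# constants: one shared mean-reverting log-deviation eta(t) mimicking
# cell-wide fluctuations (ribosome/polymerase abundance, global growth
# state). Effective rates are k * exp(eta), so positivity is guaranteed.

#' Extrinsic-noise parameters
#'
#' @param tau_c relaxation (autocorrelation) time of the OU process in
#'   seconds. A common choice is half a generation, `tau_c = 60*T/2`.
#' @param sigma stationary standard deviation of the log-deviation
#'   (dimensionless); `sigma = 0` disables the noise, and the engine is
#'   then bitwise-identical to a noiseless run under the same seed.
#' @param applied_to character vector of reaction and/or gene names whose
#'   rate constants are modulated (the same shared process for all).
#' @param shared logical, kept for interface completeness: the process is
#'   shared across all flagged rates and all genes.
#' @param eta0 initial log-deviation.
#' @return An `ou_params` object.
#' @export
ou_params <- function(tau_c, sigma = 0.1, applied_to = character(),
                      shared = TRUE, eta0 = 0) {
  stopifnot(is.numeric(tau_c), tau_c > 0, is.numeric(sigma), sigma >= 0)
  if (!isTRUE(shared))
    stop("only the shared extrinsic-noise process is supported")
  structure(list(tau_c = tau_c, sigma = sigma,
                 applied_to = as.character(applied_to), shared = TRUE,
                 eta0 = eta0),
            class = "ou_params")
}

#' One exact Ornstein-Uhlenbeck transition
#'
#' `eta' = eta e^(-dt/tau_c) + sigma sqrt(1 - e^(-2 dt/tau_c)) z`,
#' `z ~ N(0,1)` — the exact conditional distribution of the stationary OU
#' process after a lag `dt`, valid for any step size. The engine applies
#' it at every event using the elapsed inter-event time (the noise is
#' piecewise-constant between events).
#'
#' @param eta current log-deviation.
#' @param dt elapsed time in seconds (`>= 0`).
#' @param params an [ou_params()].
#' @return The updated log-deviation.
#' @export
ou_step <- function(eta, dt, params) {
  stopifnot(inherits(params, "ou_params"), dt >= 0)
  if (dt == 0) return(eta)
  decay <- exp(-dt / params$tau_c)
  eta * decay +
    params$sigma * sqrt(-expm1(-2 * dt / params$tau_c)) * stats::rnorm(1)
}

#' Apply the extrinsic-noise deviation to rate constants
#'
#' Geometric modulation `k_eff = k e^(eta)`, which keeps rates positive
#' for any real `eta`; the long-run mean of `k_eff` is `k e^(sigma^2/2)`
#' (lognormal mean).
#'
#' @param rates numeric vector of rate constants.
#' @param eta log-deviation (finite).
#' @return Scaled rates.
#' @export
apply_noise <- function(rates, eta) {
  if (!is.finite(eta)) stop("eta must be finite")
  rates * exp(eta)
}
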