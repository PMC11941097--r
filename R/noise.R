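#' Noise process specification
#'
#' Describes the stochastic current injected into the two input neurons.
#' Three families are supported:
#'
#' * `"additive_white"` — zero-mean Gaussian with standard deviation `D`
#'   (pA), resampled every `resample_dt` ms and applied as-is;
#' * `"multiplicative_white"` — the same Gaussian draw scaled by each input
#'   neuron's analog drive (input gain times input value), modeling synaptic
#'   transmission variability: strong inputs generate strong noise, inputs
#'   near zero generate almost none;
#' * `"ou_colored"` — a zero-mean Ornstein-Uhlenbeck process with
#'   mean-reversion rate `theta` (1/ms) and per-step Gaussian innovations of
#'   standard deviation `D`, giving temporally correlated noise with
#'   autocorrelation `exp(-theta * lag)`.
#'
#' In `"common"` mode a single value is drawn per step and applied to both
#' input neurons (for the multiplicative family the shared draw is still
#' scaled by each input's own drive); in `"independent"` mode each input
#' neuron receives its own draw from the same distribution.
#'
#' @param family Noise family, see above.
#' @param D Standard deviation of the Gaussian draws (pA for the additive
#'   families, dimensionless scale for the multiplicative family).
#' @param theta Mean-reversion rate of the OU process, 1/ms.
#' @param mode `"common"` or `"independent"` across the two input neurons.
#' @param seed Optional integer seed applied when currents are generated.
#' @param resample_dt Resampling interval, ms (the simulation resolution).
#' @param ou_discretization `"exact"` (default) uses the exponential
#'   propagator `exp(-theta * dt)` for the deterministic mean-reversion, so
#'   the discrete process has exactly the `exp(-theta * lag)`
#'   autocorrelation; `"euler"` uses the first-order factor
#'   `1 - theta * dt`.
#' @param ou_sqrt_dt If `TRUE`, scale the OU innovation standard deviation
#'   by `sqrt(resample_dt)` instead of using `D` per step.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(family = c("additive_white", "multiplicative_white",
                                  "ou_colored"),
                       D = 1, theta = 1, mode = c("common", "independent"),
                       seed = NULL, resample_dt = 0.1,
                       ou_discretization = c("exact", "euler"),
                       ou_sqrt_dt = FALSE) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  ou_discretization <- match.arg(ou_discretization)
  if (!is.numeric(D) || length(D) != 1L || D < 0)
    stop("D must be a single non-negative number")
  if (family == "ou_colored" && theta <= 0)
    stop("theta must be positive for OU noise")
  if (resample_dt <= 0) stop("resample_dt must be positive")
  structure(list(family = family, D = D, theta = theta, mode = mode,
                 seed = seed, resample_dt = resample_dt,
                 ou_discretization = ou_discretization,
                 ou_sqrt_dt = isTRUE(ou_sqrt_dt)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("%s noise, %s mode, D = %g", x$family, x$mode, x$D))
  if (x$family == "ou_colored")
    cat(sprintf(", theta = %g /ms (%s)", x$theta, x$ou_discretization))
  cat(sprintf(", resampled every %g ms\n", x$resample_dt))
  invisible(x)
}

#' Draw white noise values
#'
#' @param n Number of draws.
#' @param D Standard deviation (non-negative).
#' @return Numeric vector of `n` draws from `Normal(0, D^2)`.
#' @export
sample_white <- function(n, D) {
  if (!is.numeric(D) || length(D) != 1L || D < 0)
    stop("D must be a single non-negative number")
  rnorm(n, mean = 0, sd = D)
}

# per-step mean-reversion factor and innovation SD of the discretized OU
ou_coefs <- function(spec, dt) {
  a <- switch(spec$ou_discretization,
              exact = exp(-spec$theta * dt),
              euler = 1 - spec$theta * dt)
  if (a < 0) stop("theta * dt too large for the Euler discretization")
  sd <- if (spec$ou_sqrt_dt) spec$D * sqrt(dt) else spec$D
  list(a = a, sd = sd)
}

#' One step of the Ornstein-Uhlenbeck process
#'
#' Advances `z` by one resampling step: the deterministic part mean-reverts
#' toward 0 at rate `theta` and a Gaussian innovation of standard deviation
#' `D` is added.
#'
#' @param z Current value(s) of the process.
#' @param spec A [noise_spec()] with `family = "ou_colored"`.
#' @param dt Step size, ms (defaults to the spec's resampling interval).
#' @return The advanced value(s).
#' @export
step_ou <- function(z, spec, dt = spec$resample_dt) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$theta <= 0) stop("theta must be positive")
  k <- ou_coefs(spec, dt)
  z * k$a + rnorm(length(z), 0, k$sd)
}

#' Generate an Ornstein-Uhlenbeck trace
#'
#' @param n Number of steps.
#' @param spec A [noise_spec()] with `family = "ou_colored"`.
#' @param dt Step size, ms.
#' @param z0 Initial value.
#' @return Numeric vector of `n` consecutive values (excluding `z0`).
#' @export
ou_trace <- function(n, spec, dt = spec$resample_dt, z0 = 0) {
  stopifnot(inherits(spec, "noise_spec"), n >= 0)
  if (n == 0) return(numeric(0))
  k <- ou_coefs(spec, dt)
  xi <- rnorm(n, 0, k$sd)
  as.numeric(stats::filter(xi, k$a, method = "recursive", init = z0))
}

#' Noise current series for the two input neurons
#'
#' Generates `n_steps` rows of noise currents for the two input neurons
#' under a [noise_spec()].  Draws are consumed from the current RNG stream
#' unless the spec carries a `seed`, in which case the stream is restored
#' afterwards.
#'
#' @param spec A [noise_spec()].
#' @param n_steps Number of resampling steps.
#' @param drives Length-2 vector of the input neurons' analog drives
#'   (input gain times input value), pA; used only by the multiplicative
#'   family, which scales each draw by the receiving neuron's drive.
#' @return A `n_steps x 2` numeric matrix of noise currents, pA.  With
#'   `D = 0` the matrix is all zero.
#' @examples
#' ns <- noise_currents(noise_spec("additive_white", D = 5), 4)
#' all(ns[, 1] == ns[, 2])  # common mode shares the draw
#' @export
noise_currents <- function(spec, n_steps = 1, drives = c(0, 0)) {
  stopifnot(inherits(spec, "noise_spec"), length(drives) == 2L, n_steps >= 0)
  with_local_seed(spec$seed, {
    raw <- if (spec$mode == "common") {
      z <- switch(spec$family,
                  ou_colored = ou_trace(n_steps, spec),
                  sample_white(n_steps, spec$D))
      cbind(z, z, deparse.level = 0)
    } else {
      switch(spec$family,
             ou_colored = cbind(ou_trace(n_steps, spec),
                                ou_trace(n_steps, spec)),
             matrix(sample_white(2 * n_steps, spec$D), ncol = 2))
    }
    if (spec$family == "multiplicative_white")
      raw <- sweep(raw, 2, drives, `*`)
    raw
  })
}
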