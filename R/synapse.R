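#' Synapse parameters
#'
#' Static synapses inject a fixed-amplitude exponential postsynaptic current
#' (PSC) on every presynaptic spike.  Dynamical synapses follow the
#' Tsodyks-Markram short-term plasticity model: a finite pool of synaptic
#' resources is partitioned into recovered (`x`), active and inactive
#' fractions; each presynaptic spike first facilitates the utilization
#' (`u <- u + U * (1 - u)`), then releases the fraction `u * x` of the
#' recovered pool into the active pool, which feeds the PSC
#' (`I_psc <- I_psc + weight * r`).  Between spikes `u` relaxes to 0 with
#' `tau_fac`, the active pool (and hence the PSC) decays with `tau_syn`, and
#' inactive resources recover with `tau_rec`.
#'
#' @param weight Signed PSC amplitude, pA, for a full (unit-fraction) release.
#'   Negative weights implement inhibition.
#' @param kind `"dynamical"` (Tsodyks-Markram) or `"static"`.
#' @param U Baseline utilization in `[0, 1]` (facilitation increment).
#' @param tau_fac Facilitation time constant, ms.
#' @param tau_rec Resource recovery time constant, ms.
#' @param tau_syn PSC decay time constant, ms.  Larger values integrate
#'   presynaptic activity over a longer window; the time integral of a
#'   single PSC is `|weight * r| * tau_syn`.
#' @return An object of class `"synapse_params"`.
#' @export
synapse_params <- function(weight = 1, kind = c("dynamical", "static"),
                           U = 0.5, tau_fac = 1, tau_rec = 10, tau_syn = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(weight), length(weight) == 1L, is.finite(weight))
  if (tau_syn <= 0) stop("tau_syn must be positive")
  if (tau_rec <= 0) stop("tau_rec must be positive")
  if (tau_fac <= 0) stop("tau_fac must be positive")
  if (U < 0 || U > 1) stop("U must lie in [0, 1]")
  structure(list(weight = weight, kind = kind, U = U, tau_fac = tau_fac,
                 tau_rec = tau_rec, tau_syn = tau_syn),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf("%s synapse: weight = %g pA, tau_syn = %g ms\n",
              x$kind, x$weight, x$tau_syn))
  if (x$kind == "dynamical")
    cat(sprintf("  U = %g, tau_fac = %g ms, tau_rec = %g ms\n",
                x$U, x$tau_fac, x$tau_rec))
  invisible(x)
}

#' Synapse state
#'
#' @param u Current utilization in `[0, 1]`.
#' @param x Recovered resource fraction in `[0, 1]`.
#' @param I_psc Current postsynaptic current, pA (signed; equals
#'   `weight` times the active resource fraction for a dynamical synapse).
#' @return An object of class `"synapse_state"`.
#' @export
synapse_state <- function(u = 0, x = 1, I_psc = 0) {
  stopifnot(u >= 0, u <= 1, x >= 0, x <= 1)
  structure(list(u = u, x = x, I_psc = I_psc), class = "synapse_state")
}

# active resource fraction implied by the PSC; 0 when the synapse carries no
# weight (nothing was ever released)
active_fraction <- function(state, params) {
  if (params$weight == 0) 0 else state$I_psc / params$weight
}

#' Relax a synapse between spikes
#'
#' Advances the synapse state by `dt` milliseconds with no presynaptic
#' spike.  The PSC decays exponentially with `tau_syn`; for a dynamical
#' synapse the utilization relaxes toward 0 with `tau_fac` and resources
#' recover toward 1 with `tau_rec`.  Recovery follows the three-state
#' resource formulation: active resources first become inactive as the PSC
#' decays and then rejoin the recovered pool, so recovered + active +
#' inactive always sum to 1.
#'
#' @param state A [synapse_state()].
#' @param params A [synapse_params()].
#' @param dt Elapsed time, ms (`dt = 0` returns the state unchanged).
#' @return The relaxed [synapse_state()].
#' @export
decay_psc <- function(state, params, dt) {
  stopifnot(inherits(state, "synapse_state"),
            inherits(params, "synapse_params"), dt >= 0)
  if (dt == 0) return(state)
  e_syn <- exp(-dt / params$tau_syn)
  if (params$kind == "static")
    return(synapse_state(state$u, state$x, state$I_psc * e_syn))
  y <- active_fraction(state, params)
  tr <- params$tau_rec
  if (abs(tr - params$tau_syn) < 1e-9 * params$tau_syn)
    tr <- params$tau_syn * (1 + 1e-9)
  c1 <- params$tau_syn / (tr - params$tau_syn)
  e_rec <- exp(-dt / params$tau_rec)
  B <- y * c1
  x_new <- 1 + (state$x - 1 - B) * e_rec + B * e_syn
  synapse_state(state$u * exp(-dt / params$tau_fac),
                min(max(x_new, 0), 1),
                state$I_psc * e_syn)
}

#' Apply a presynaptic spike
#'
#' For a dynamical synapse: facilitate (`u <- u + U * (1 - u)`), release
#' the fraction `u * x` from the recovered pool, and add `weight`
#' times that fraction to the PSC.
#' For a static synapse the PSC is incremented by the full `weight` and the
#' resource variables are untouched.
#'
#' @param state A [synapse_state()].
#' @param params A [synapse_params()].
#' @return The updated [synapse_state()] with attribute `"release"` holding
#'   the released fraction (1 for a static synapse).
#' @examples
#' s <- on_presynaptic_spike(synapse_state(), synapse_params(weight = 100))
#' s$u          # 0.5
#' s$I_psc      # 50
#' @export
on_presynaptic_spike <- function(state, params) {
  stopifnot(inherits(state, "synapse_state"),
            inherits(params, "synapse_params"))
  if (params$kind == "static") {
    out <- synapse_state(state$u, state$x, state$I_psc + params$weight)
    attr(out, "release") <- 1
    return(out)
  }
  u <- state$u + params$U * (1 - state$u)
  r <- u * state$x
  out <- synapse_state(u, state$x - r, state$I_psc + params$weight * r)
  attr(out, "release") <- r
  out
}

#' Release fractions along a spike train
#'
#' Drives a synapse from rest through a sorted train of presynaptic spike
#' times and returns the released resource fraction at each spike.  Under
#' sustained drive with `tau_rec` much longer than the inter-spike interval
#' the sequence is depressing (non-increasing after the first spike); widely
#' separated spikes release the same fraction.
#'
#' @param times Sorted numeric vector of spike times, ms.
#' @param params A [synapse_params()].
#' @return Numeric vector of release fractions, one per spike (all 1 for a
#'   static synapse).
#' @examples
#' synapse_release_train(seq(0, 90, by = 10), synapse_params())
#' @export
synapse_release_train <- function(times, params) {
  stopifnot(inherits(params, "synapse_params"))
  times <- as.numeric(times)
  if (length(times) == 0L) return(numeric(0))
  if (is.unsorted(times)) stop("spike times must be sorted")
  state <- synapse_state()
  rel <- numeric(length(times))
  t_prev <- times[1L]
  for (i in seq_along(times)) {
    state <- decay_psc(state, params, times[i] - t_prev)
    state <- on_presynaptic_spike(state, params)
    rel[i] <- attr(state, "release")
    t_prev <- times[i]
  }
  rel
}
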