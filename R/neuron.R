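#' Integrate-and-fire neuron parameters
#'
#' Bundles the constants of a (leaky) integrate-and-fire neuron with
#' exponential postsynaptic currents.  The defaults are the reference
#' configuration used throughout the package: a 10 pF / 10 ms membrane
#' resting at 0 mV, threshold 20 mV, reset 16 mV, and a constant bias
#' current of 18 pA.  With `C_m = 10` pF and `tau_m = 10` ms the implied
#' membrane resistance is 1 GOhm, so currents in pA map one-to-one onto
#' asymptotic depolarization in mV: a constant 18 pA drive settles at
#' 18 mV, just below threshold.  That sub-threshold operating point is the
#' substrate for stochastic resonance: noise-free, the neuron is silent;
#' noise occasionally lifts the membrane over the 2 mV gap.
#'
#' @param C_m Membrane capacitance, pF.
#' @param tau_m Membrane time constant, ms.
#' @param E_L Resting membrane potential, mV.
#' @param V_reset Post-spike reset potential, mV.  Note the default sits
#'   *above* rest, so after a spike the membrane restarts only 4 mV below
#'   threshold.
#' @param V_th Spike threshold, mV.
#' @param V_min Lower clamp on the membrane potential, mV.
#' @param I_e Constant input current, pA (the 18 pA base; per-neuron biases
#'   are added on top by the circuit).
#' @param t_ref Absolute refractory period, ms, during which the membrane is
#'   clamped at `V_reset`.
#' @param leaky If `FALSE`, the leak term is dropped and the membrane
#'   integrates its drive linearly (`dV = I * dt / tau_m`).
#' @param refractory_input_discarded If `FALSE` (default), synaptic and noise
#'   input keeps driving the postsynaptic-current state during refractoriness
#'   even though the membrane itself is clamped.
#' @return An object of class `"lif_params"`.
#' @examples
#' p <- lif_params()
#' free_decay(10, p, dt = p$tau_m)  # 10 / e
#' @export
lif_params <- function(C_m = 10, tau_m = 10, E_L = 0, V_reset = 16,
                       V_th = 20, V_min = -1.798e308, I_e = 18, t_ref = 2,
                       leaky = TRUE, refractory_input_discarded = FALSE) {
  stopifnot(is.numeric(C_m), C_m > 0, is.numeric(tau_m), tau_m > 0)
  if (!(V_reset < V_th)) stop("V_reset must lie below V_th")
  if (!(V_min <= V_reset)) stop("V_min must not exceed V_reset")
  if (t_ref < 0) stop("t_ref must be non-negative")
  structure(list(C_m = C_m, tau_m = tau_m, E_L = E_L, V_reset = V_reset,
                 V_th = V_th, V_min = V_min, I_e = I_e, t_ref = t_ref,
                 leaky = isTRUE(leaky),
                 refractory_input_discarded = isTRUE(refractory_input_discarded)),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(if (x$leaky) "Leaky" else "Non-leaky",
      "integrate-and-fire neuron\n")
  cat(sprintf("  tau_m = %g ms, C_m = %g pF, E_L = %g mV\n",
              x$tau_m, x$C_m, x$E_L))
  cat(sprintf("  V_th = %g mV, V_reset = %g mV, t_ref = %g ms, I_e = %g pA\n",
              x$V_th, x$V_reset, x$t_ref, x$I_e))
  invisible(x)
}

#' Instantaneous neuron state
#'
#' @param V_m Membrane potential, mV.
#' @param refractory_remaining Remaining refractory time, ms.
#' @param spike_count Number of spikes emitted so far.
#' @return An object of class `"neuron_state"`.
#' @export
neuron_state <- function(V_m = 0, refractory_remaining = 0, spike_count = 0L) {
  stopifnot(refractory_remaining >= 0, spike_count >= 0)
  structure(list(V_m = V_m, refractory_remaining = refractory_remaining,
                 spike_count = as.integer(spike_count)),
            class = "neuron_state")
}

#' Free membrane relaxation
#'
#' Relaxes a membrane potential toward the resting potential for `dt`
#' milliseconds with no input: `E_L + (V - E_L) * exp(-dt / tau_m)`.
#'
#' @param V Membrane potential, mV.
#' @param params A [lif_params()] object (must be leaky).
#' @param dt Elapsed time, ms (`dt = 0` returns `V` unchanged).
#' @return The relaxed potential, mV.
#' @export
free_decay <- function(V, params, dt) {
  stopifnot(inherits(params, "lif_params"), dt >= 0)
  if (!params$leaky) stop("free_decay is defined for the leaky neuron")
  params$E_L + (V - params$E_L) * exp(-dt / params$tau_m)
}

#' Advance one neuron by one time step
#'
#' One step of the clock-driven integration scheme.  Outside refractoriness
#' the membrane follows the exact exponential propagator of the linear
#' membrane equation with the total drive `I_e + I_syn + I_noise` held
#' constant over the step (the non-leaky variant integrates the drive
#' linearly).  Threshold crossing emits a spike, resets the membrane to
#' `V_reset` and starts the refractory clock; while refractory the membrane
#' stays clamped at `V_reset` and the step consumes `dt` of refractory time.
#'
#' @param state A [neuron_state()].
#' @param params A [lif_params()].
#' @param I_syn Synaptic input current, pA.
#' @param I_noise Noise input current, pA.
#' @param dt Step size, ms (must be positive).
#' @return A list with elements `state` (the advanced [neuron_state()]) and
#'   `spiked` (logical).
#' @examples
#' st <- neuron_state(V_m = 19.95)
#' step_neuron(st, lif_params(), I_syn = 10, I_noise = 0, dt = 0.1)$spiked
#' @export
step_neuron <- function(state, params, I_syn = 0, I_noise = 0, dt = 0.1) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "lif_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  if (!all(is.finite(c(I_syn, I_noise)))) stop("currents must be finite")
  if (state$refractory_remaining > 1e-9) {
    rem <- state$refractory_remaining - dt
    if (rem < 1e-9) rem <- 0   # guard float accumulation over dt-steps
    return(list(state = neuron_state(params$V_reset, rem, state$spike_count),
                spiked = FALSE))
  }
  I_tot <- params$I_e + I_syn + I_noise
  V <- if (params$leaky) {
    e_m <- exp(-dt / params$tau_m)
    params$E_L + (state$V_m - params$E_L) * e_m + I_tot * (1 - e_m)
  } else {
    state$V_m + I_tot * dt / params$tau_m
  }
  V <- max(V, params$V_min)
  if (V >= params$V_th) {
    list(state = neuron_state(params$V_reset, params$t_ref,
                              state$spike_count + 1L),
         spiked = TRUE)
  } else {
    list(state = neuron_state(V, 0, state$spike_count), spiked = FALSE)
  }
}

#' Simulate a single neuron against a drive series
#'
#' Runs one neuron on the simulation clock against a per-step series of
#' input currents (synaptic plus noise, pA) and returns the ordered spike
#' times.  The run is deterministic given the drive series.
#'
#' @param params A [lif_params()].
#' @param drive Numeric vector of per-step input currents, pA (added to
#'   `I_e`).  An empty series yields no spikes.
#' @param dt Step size, ms.
#' @param V0 Initial membrane potential, mV.
#' @return Numeric vector of spike times, ms (end of the step in which the
#'   threshold was crossed).
#' @examples
#' # constant supra-threshold drive: regular firing
#' run_neuron_train(lif_params(), rep(7, 1000), dt = 0.1)
#' @export
run_neuron_train <- function(params, drive, dt = 0.1, V0 = 0) {
  stopifnot(inherits(params, "lif_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  drive <- as.numeric(drive)
  if (length(drive) == 0L) return(numeric(0))
  if (!all(is.finite(drive))) stop("drive series must be finite")
  sim_neuron_cpp(drive, params$tau_m, params$E_L, params$I_e, params$V_reset,
                 params$V_th, params$V_min, params$t_ref, params$leaky,
                 V0, dt)
}
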