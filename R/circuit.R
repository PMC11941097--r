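#' Canonical XOR weight template
#'
#' The dimensionless 2-2-1 connection template used by both circuits before
#' gain scaling: hidden unit H1 computes `+x0 - x1`, H2 computes
#' `-x0 + x1`, and the output sums the two hidden units.  With ReLU (or
#' rectifying spiking) nonlinearities the pair encodes the two half-wave
#' rectified input differences, so the output responds to `|x0 - x1|`.
#' All biases default to zero.
#'
#' @param hidden 2 x 2 matrix of input-to-hidden weights (rows = hidden
#'   units, columns = inputs).
#' @param output Length-2 vector of hidden-to-output weights.
#' @param bias Length-5 vector of per-neuron biases, pA, in the order
#'   input0, input1, hidden1, hidden2, output.
#' @return A list of class `"xor_template"`.
#' @export
xor_template <- function(hidden = matrix(c(1, -1, -1, 1), nrow = 2,
                                         byrow = TRUE),
                         output = c(1, 1), bias = rep(0, 5)) {
  stopifnot(is.matrix(hidden), all(dim(hidden) == c(2L, 2L)),
            length(output) == 2L, length(bias) == 5L,
            all(is.finite(hidden)), all(is.finite(output)),
            all(is.finite(bias)))
  structure(list(hidden = hidden, output = output, bias = bias),
            class = "xor_template")
}

validate_gains <- function(input_gain, weight_gain, bias_gain) {
  stopifnot(is.numeric(input_gain), length(input_gain) == 1L,
            is.numeric(weight_gain), length(weight_gain) == 1L,
            is.numeric(bias_gain), length(bias_gain) == 1L)
  if (input_gain <= 0) stop("input_gain must be positive")
  if (weight_gain < 0) stop("weight_gain must be non-negative")
}

#' Build the spiking XOR circuit
#'
#' Constructs the five-neuron spiking circuit: two input neurons receiving
#' the analog drive `input_gain * x_i` (plus the 18 pA base current, the
#' bias, and any noise current), a hidden pair wired with the antisymmetric
#' template, and one output neuron.  Connection weights are the template
#' entries scaled by `weight_gain` (pA of PSC amplitude); inhibitory
#' template entries become negative PSC amplitudes through the same synapse
#' model.  Every connection carries a one-step (0.1 ms) transmission delay.
#'
#' @param input_gain Multiplier mapping the analog input in `[0, 1]` to a
#'   constant injected current, pA.
#' @param weight_gain Multiplier applied to the template weights, pA.
#' @param bias_gain Multiplier applied to the template biases (default 1).
#' @param synapse `"dynamical"` (Tsodyks-Markram) or `"static"`.
#' @param tau_syn PSC decay time constant, ms.
#' @param U,tau_fac,tau_rec Short-term plasticity parameters, see
#'   [synapse_params()].
#' @param neuron A [lif_params()] object shared by all five neurons.
#' @param template An [xor_template()].
#' @return An object of class `"snn_circuit"`.
#' @examples
#' circ <- snn_circuit(input_gain = 5, weight_gain = 110)
#' run_snn(circ, 1, 0, T = 0.5)$counts
#' @export
snn_circuit <- function(input_gain = 5, weight_gain = 110, bias_gain = 1,
                        synapse = c("dynamical", "static"), tau_syn = 1,
                        U = 0.5, tau_fac = 1, tau_rec = 10,
                        neuron = lif_params(), template = xor_template()) {
  synapse <- match.arg(synapse)
  validate_gains(input_gain, weight_gain, bias_gain)
  if (tau_syn <= 0) stop("tau_syn must be positive")
  stopifnot(inherits(neuron, "lif_params"), inherits(template, "xor_template"))
  structure(list(input_gain = input_gain, weight_gain = weight_gain,
                 bias_gain = bias_gain, synapse = synapse, tau_syn = tau_syn,
                 U = U, tau_fac = tau_fac, tau_rec = tau_rec,
                 neuron = neuron, template = template),
            class = "snn_circuit")
}

#' @export
print.snn_circuit <- function(x, ...) {
  cat("2-2-1 spiking XOR circuit\n")
  cat(sprintf("  input_gain = %g, weight_gain = %g, bias_gain = %g\n",
              x$input_gain, x$weight_gain, x$bias_gain))
  cat(sprintf("  %s synapses, tau_syn = %g ms\n", x$synapse, x$tau_syn))
  invisible(x)
}

#' Build the ReLU XOR circuit
#'
#' The non-spiking counterpart of [snn_circuit()]: a 2-2-1 network of ReLU
#' units sharing the same template and gain scaling.  Hidden activations are
#' `ReLU(weight_gain * W %*% (input_gain * x + noise) + bias)` and the
#' output is the ReLU of the weighted hidden sum.
#'
#' @inheritParams snn_circuit
#' @return An object of class `"ann_circuit"`.
#' @export
ann_circuit <- function(input_gain = 5, weight_gain = 110, bias_gain = 1,
                        template = xor_template()) {
  validate_gains(input_gain, weight_gain, bias_gain)
  stopifnot(inherits(template, "xor_template"))
  structure(list(input_gain = input_gain, weight_gain = weight_gain,
                 bias_gain = bias_gain, template = template),
            class = "ann_circuit")
}

#' @export
print.ann_circuit <- function(x, ...) {
  cat("2-2-1 ReLU XOR circuit\n")
  cat(sprintf("  input_gain = %g, weight_gain = %g, bias_gain = %g\n",
              x$input_gain, x$weight_gain, x$bias_gain))
  invisible(x)
}

#' Forward pass of the ReLU circuit
#'
#' Computes the output activation for one or more input pairs, optionally
#' perturbing the scaled input drive with noise currents.  Negative
#' intermediate values are clipped by the ReLU.
#'
#' @param circuit An [ann_circuit()].
#' @param x0,x1 Input values (vectors of equal length).
#' @param noise Optional `length(x0) x 2` matrix of noise currents added to
#'   the scaled input drives.
#' @return Numeric vector of output activations.
#' @export
ann_forward <- function(circuit, x0, x1, noise = NULL) {
  stopifnot(inherits(circuit, "ann_circuit"), length(x0) == length(x1))
  tm <- circuit$template
  drive <- cbind(circuit$input_gain * x0, circuit$input_gain * x1)
  if (!is.null(noise)) {
    noise <- as.matrix(noise)
    stopifnot(nrow(noise) == length(x0), ncol(noise) == 2L)
    drive <- drive + noise
  }
  hb <- circuit$bias_gain * tm$bias[3:4]
  hidden <- pmax(circuit$weight_gain * (drive %*% t(tm$hidden)) +
                   rep(hb, each = length(x0)), 0)
  out <- circuit$weight_gain * (hidden %*% tm$output) +
    circuit$bias_gain * tm$bias[5L]
  pmax(as.numeric(out), 0)
}

#' Noise-averaged ReLU output
#'
#' The analog circuit has no internal dynamics, so noise is evaluated by
#' Monte Carlo: the forward pass is repeated over `n_draws` independent
#' noise draws and the outputs are averaged.
#'
#' @param circuit An [ann_circuit()].
#' @param x0,x1 One input pair.
#' @param spec A [noise_spec()]; `D = 0` reduces to the noiseless forward
#'   value.
#' @param n_draws Number of noise draws to average.
#' @param seed Optional integer seed (RNG stream restored afterwards).
#' @return The averaged output activation (scalar).
#' @export
ann_noise_average <- function(circuit, x0, x1, spec, n_draws = 20000,
                              seed = NULL) {
  stopifnot(inherits(circuit, "ann_circuit"), inherits(spec, "noise_spec"),
            length(x0) == 1L, length(x1) == 1L, n_draws >= 1)
  with_local_seed(seed, {
    drives <- circuit$input_gain * c(x0, x1)
    noise <- noise_currents(spec, n_steps = n_draws, drives = drives)
    mean(ann_forward(circuit, rep(x0, n_draws), rep(x1, n_draws), noise))
  })
}

#' Run the spiking circuit on one input pair
#'
#' Advances all five neurons and six synapses on the simulation clock for
#' `T` seconds.  The input neurons receive the constant analog drive
#' `input_gain * x_i` plus, when a [noise_spec()] is supplied, a noise
#' current resampled every step.  Returns the per-neuron spike counts; the
#' output neuron's count is the circuit's raw decision statistic.
#'
#' @param circuit An [snn_circuit()].
#' @param x0,x1 One input pair in `[0, 1]` (values outside are allowed and
#'   simply scale the drive).
#' @param noise Optional [noise_spec()]; `NULL` or `D = 0` runs noise-free
#'   (and hence fully deterministically).
#' @param T Simulation time, seconds.
#' @param dt Simulation resolution, ms.
#' @param seed Optional integer seed for the noise draws (RNG stream
#'   restored afterwards).
#' @param record_spikes If `TRUE`, also return the per-neuron spike times.
#' @return An object of class `"snn_result"`: a list with `counts` (named,
#'   neurons N1..N5), `rates` (Hz), `T`, `dt`, and optionally `spikes`.
#' @examples
#' circ <- snn_circuit(input_gain = 5, weight_gain = 110)
#' run_snn(circ, 1, 0, T = 1)$rates
#' @export
run_snn <- function(circuit, x0, x1, noise = NULL, T = 20, dt = 0.1,
                    seed = NULL, record_spikes = FALSE) {
  stopifnot(inherits(circuit, "snn_circuit"), length(x0) == 1L,
            length(x1) == 1L, T > 0, dt > 0)
  n_steps <- as.integer(round(T * 1000 / dt))
  drives <- circuit$input_gain * c(x0, x1)
  noise_mat <- matrix(numeric(0), nrow = 0, ncol = 2)
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (noise$D > 0)
      noise_mat <- with_local_seed(seed,
                                   noise_currents(noise, n_steps, drives))
  }
  tm <- circuit$template
  w <- circuit$weight_gain * c(tm$hidden[1, 1], tm$hidden[1, 2],
                               tm$hidden[2, 1], tm$hidden[2, 2],
                               tm$output[1], tm$output[2])
  np <- circuit$neuron
  res <- sim_xor_point_cpp(drives[1], drives[2],
                           circuit$bias_gain * tm$bias, w,
                           np$tau_m, np$E_L, np$I_e, np$V_reset, np$V_th,
                           np$V_min, np$t_ref, np$leaky,
                           circuit$synapse == "dynamical", circuit$U,
                           circuit$tau_fac, circuit$tau_rec, circuit$tau_syn,
                           dt, n_steps, noise_mat, record_spikes)
  counts <- setNames(res$counts, paste0("N", 1:5))
  out <- list(counts = counts, rates = counts / T, T = T, dt = dt,
              x0 = x0, x1 = x1)
  if (record_spikes) out$spikes <- setNames(res$spikes, paste0("N", 1:5))
  structure(out, class = "snn_result")
}

#' @export
print.snn_result <- function(x, ...) {
  cat(sprintf("spiking XOR run: (x0, x1) = (%g, %g), T = %g s\n",
              x$x0, x$x1, x$T))
  print(x$counts)
  invisible(x)
}

#' Simulate repeated runs of the spiking circuit
#'
#' `simulate()` method wrapping [run_snn()]: repeats the simulation `nsim`
#' times with per-repeat seeds derived from `seed` and returns the spike
#' counts as a data frame (one row per repeat).  Noise-free runs are
#' deterministic, so all rows coincide when `noise` is `NULL` or `D = 0`.
#'
#' @param object An [snn_circuit()].
#' @param nsim Number of repeats.
#' @param seed Optional base seed.
#' @param x0,x1 Input pair.
#' @param noise Optional [noise_spec()].
#' @param T,dt Simulation time (s) and resolution (ms).
#' @param ... Unused.
#' @return A data frame with columns `sim`, `N1`..`N5`.
#' @export
simulate.snn_circuit <- function(object, nsim = 1, seed = NULL,
                                 x0 = 1, x1 = 0, noise = NULL,
                                 T = 20, dt = 0.1, ...) {
  rows <- lapply(seq_len(nsim), function(i) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    run_snn(object, x0, x1, noise = noise, T = T, dt = dt, seed = s)$counts
  })
  cbind(data.frame(sim = seq_len(nsim)),
        as.data.frame(do.call(rbind, rows)))
}

#' Write spike trains as plain text
#'
#' Exports a recorded run as a two-column table (neuron id, spike time in
#' ms), one row per spike.
#'
#' @param result An [run_snn()] result with `record_spikes = TRUE`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spike_train <- function(result, path) {
  stopifnot(inherits(result, "snn_result"))
  if (is.null(result$spikes))
    stop("run_snn must be called with record_spikes = TRUE")
  df <- do.call(rbind, lapply(seq_along(result$spikes), function(i) {
    tt <- result$spikes[[i]]
    if (length(tt) == 0L) return(NULL)
    data.frame(neuron = i, time_ms = tt)
  }))
  if (is.null(df)) df <- data.frame(neuron = integer(0), time_ms = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
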