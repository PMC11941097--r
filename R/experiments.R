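#' Uniform input grid over the unit square
#'
#' @param n Points per axis (default 21, i.e. step 0.05).
#' @return A data frame with columns `x0`, `x1` in fixed row-major order
#'   (`x0` varying fastest).
#' @export
xor_grid <- function(n = 21) {
  stopifnot(n >= 2)
  s <- seq(0, 1, length.out = n)
  expand.grid(x0 = s, x1 = s, KEEP.OUT.ATTRS = FALSE)
}

#' Simulate the output surface over an input grid
#'
#' Runs the circuit on every grid point and collects the raw decision
#' statistic (output-neuron spike count for the spiking circuit,
#' noise-averaged activation for the ReLU circuit) together with its
#' grid-normalized version.  A single seed set at the start makes the whole
#' surface reproducible; points are traversed in the grid's fixed row-major
#' order, each consuming its own noise draws from the stream.
#'
#' @param circuit An [snn_circuit()] or [ann_circuit()].
#' @param grid Input grid data frame (columns `x0`, `x1`).
#' @param noise Optional [noise_spec()].
#' @param T Simulation time per input, seconds (spiking circuit).
#' @param dt Simulation resolution, ms.
#' @param n_draws Noise draws averaged per input (ReLU circuit).
#' @param seed Optional integer seed (RNG stream restored afterwards).
#' @return An object of class `"xor_surface"`: the grid with columns `raw`,
#'   `norm` and (for the spiking circuit) `rate` in Hz, plus metadata
#'   attributes.
#' @examples
#' circ <- ann_circuit(input_gain = 6, weight_gain = 111)
#' surf <- simulate_surface(circ, xor_grid(11))
#' plot(surf)
#' @export
simulate_surface <- function(circuit, grid = xor_grid(21), noise = NULL,
                             T = 20, dt = 0.1, n_draws = 20000, seed = NULL) {
  stopifnot(is.data.frame(grid), all(c("x0", "x1") %in% names(grid)))
  raw <- with_local_seed(seed, {
    if (inherits(circuit, "ann_circuit")) {
      if (is.null(noise) || noise$D == 0) {
        ann_forward(circuit, grid$x0, grid$x1)
      } else {
        vapply(seq_len(nrow(grid)), function(i)
          ann_noise_average(circuit, grid$x0[i], grid$x1[i], noise,
                            n_draws = n_draws), numeric(1))
      }
    } else if (inherits(circuit, "snn_circuit")) {
      vapply(seq_len(nrow(grid)), function(i)
        unname(run_snn(circuit, grid$x0[i], grid$x1[i], noise = noise,
                       T = T, dt = dt)$counts[5L]), numeric(1))
    } else stop("circuit must be an snn_circuit or ann_circuit")
  })
  df <- data.frame(grid[c("x0", "x1")], raw = raw,
                   norm = normalize_surface(raw))
  if (inherits(circuit, "snn_circuit")) df$rate <- raw / T
  structure(df, class = c("xor_surface", "data.frame"),
            circuit = circuit, noise = noise, T = T, dt = dt)
}

#' @export
print.xor_surface <- function(x, ...) {
  cat(sprintf("XOR output surface: %d input points, max raw statistic %g\n",
              nrow(x), max(x$raw)))
  print(utils::head(as_surface_df(x)))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Reshape a surface column into a matrix
#'
#' @param x An `"xor_surface"`.
#' @param value Column to reshape (default `"norm"`).
#' @param ... Unused.
#' @return A matrix with `x0` along rows and `x1` along columns, with the
#'   axis values as dimnames.
#' @export
as.matrix.xor_surface <- function(x, value = "norm", ...) {
  x0v <- sort(unique(x$x0))
  x1v <- sort(unique(x$x1))
  m <- matrix(NA_real_, length(x0v), length(x1v),
              dimnames = list(x0 = format(x0v), x1 = format(x1v)))
  m[cbind(match(x$x0, x0v), match(x$x1, x1v))] <- x[[value]]
  m
}

#' @export
plot.xor_surface <- function(x, value = "norm", ...) {
  m <- as.matrix(x, value = value)
  image(sort(unique(x$x0)), sort(unique(x$x1)), m,
        xlab = "x0", ylab = "x1", main = paste("XOR surface:", value), ...)
  invisible(x)
}

#' Output firing-rate map
#'
#' Convenience wrapper returning the output neuron's firing rate (Hz) over
#' the input grid as a matrix suitable for heatmap rendering or CSV export
#' via [utils::write.csv()].
#'
#' @inheritParams simulate_surface
#' @return A numeric matrix (`x0` by `x1`) of firing rates in Hz.
#' @export
firing_rate_map <- function(circuit, grid = xor_grid(21), noise = NULL,
                            T = 20, dt = 0.1, seed = NULL) {
  stopifnot(inherits(circuit, "snn_circuit"))
  surf <- simulate_surface(circuit, grid, noise = noise, T = T, dt = dt,
                           seed = seed)
  as.matrix(surf, value = "rate")
}

#' Grid search over input and weight gains
#'
#' Exhaustively evaluates gain combinations for either circuit on a
#' noise-free surface.  For each combination the circuit is built, its
#' output surface simulated, and the accuracy computed either at a fixed
#' decision boundary or (default) as the best over a boundary grid search.
#' Ties are broken toward the smallest `(input_gain, weight_gain)`
#' lexicographically.
#'
#' @param kind `"snn"` or `"ann"`.
#' @param input_gains,weight_gains Candidate gain values.
#' @param boundary Either `NULL` (search boundaries with [fit_boundary()])
#'   or a fixed `c(b, h)` pair.
#' @param grid Input grid.
#' @param T,dt Simulation time (s) and resolution (ms) for the spiking
#'   circuit.
#' @param b,h Boundary candidates used when `boundary` is `NULL`.
#' @param circuit_args Extra arguments passed to [snn_circuit()] /
#'   [ann_circuit()] (e.g. `synapse`, `tau_syn`).
#' @param progress Print one line per input gain.
#' @return An object of class `"gain_search"`: a list with `results` (one
#'   row per combination: gains, accuracy, best `b`, `h`) and `best` (the
#'   winning row).
#' @export
grid_search_gains <- function(kind = c("snn", "ann"),
                              input_gains = 1:10,
                              weight_gains = seq(5, 150, by = 5),
                              boundary = NULL, grid = xor_grid(21),
                              T = 5, dt = 0.1,
                              b = seq(0.02, 0.98, by = 0.02),
                              h = seq(0.02, 0.98, by = 0.02),
                              circuit_args = list(), progress = FALSE) {
  kind <- match.arg(kind)
  if (length(input_gains) == 0 || length(weight_gains) == 0)
    stop("gain grid must be non-empty")
  combos <- expand.grid(input_gain = input_gains, weight_gain = weight_gains,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$input_gain, combos$weight_gain), ]
  res <- lapply(seq_len(nrow(combos)), function(i) {
    ig <- combos$input_gain[i]
    wg <- combos$weight_gain[i]
    if (progress && wg == weight_gains[1])
      message(sprintf("input_gain = %g ...", ig))
    circ <- do.call(if (kind == "snn") snn_circuit else ann_circuit,
                    c(list(input_gain = ig, weight_gain = wg), circuit_args))
    # silent circuits are expected for weak gains; skip them quietly
    surf <- suppressWarnings(simulate_surface(circ, grid, noise = NULL,
                                              T = T, dt = dt))
    if (max(surf$raw) == 0)
      return(data.frame(input_gain = ig, weight_gain = wg, accuracy = NA,
                        b = NA, h = NA))
    if (is.null(boundary)) {
      fit <- fit_boundary(surf, b = b, h = h)
      data.frame(input_gain = ig, weight_gain = wg, accuracy = fit$accuracy,
                 b = fit$b, h = fit$h)
    } else {
      acc <- xor_accuracy(surf$norm, surf$x0, surf$x1,
                          boundary[1], boundary[2])
      data.frame(input_gain = ig, weight_gain = wg, accuracy = acc,
                 b = boundary[1], h = boundary[2])
    }
  })
  results <- suppressWarnings(do.call(rbind, res))
  ok <- !is.na(results$accuracy)
  if (!any(ok)) stop("every gain combination produced a silent circuit")
  best_i <- which(ok)[order(-results$accuracy[ok], results$input_gain[ok],
                            results$weight_gain[ok])[1L]]
  structure(list(results = results, best = results[best_i, ],
                 kind = kind, boundary = boundary),
            class = "gain_search")
}

#' @export
print.gain_search <- function(x, ...) {
  cat(sprintf("Gain grid search (%s circuit), %d combinations\n",
              toupper(x$kind), nrow(x$results)))
  cat(sprintf("  best: input_gain = %g, weight_gain = %g, accuracy = %.2f%% at (b, h) = (%.2f, %.2f)\n",
              x$best$input_gain, x$best$weight_gain, 100 * x$best$accuracy,
              x$best$b, x$best$h))
  invisible(x)
}

#' Noise sweep configuration
#'
#' Bundles the full protocol of a noise sweep.  The defaults reproduce the
#' reference protocol: 20 s of simulation per input at 0.1 ms resolution
#' (200,000 noise samples per input), 20 repeats per noise level with a
#' fresh seed per repeat, and 20,000 averaged noise draws for the analog
#' circuit.  Tests and quick exploration pass smaller `T` and `repeats`.
#'
#' @param noise_family,mode,theta See [noise_spec()].
#' @param D Vector of noise intensities to sweep.
#' @param boundaries Data frame (or 2-column matrix) of decision boundaries
#'   `(b, h)` to track across noise levels.
#' @param input_gain,weight_gain,bias_gain Circuit gains.
#' @param synapse,tau_syn,U,tau_fac,tau_rec Synapse configuration.
#' @param repeats Repeats per noise level.
#' @param T Simulation time per input, seconds.
#' @param dt Resolution, ms.
#' @param n_draws Averaged noise draws per input for the analog circuit.
#' @param grid_n Input grid points per axis.
#' @param base_seed Base seed; run `(i, r)` (noise level `i`, repeat `r`)
#'   uses `base_seed + 1000 * (i - 1) + (r - 1)`, and all boundaries share
#'   that run's noise realization.
#' @return An object of class `"sweep_config"` (a named list).
#' @export
sweep_config <- function(noise_family = "multiplicative_white",
                         mode = "common", D = c(0, 1, 2, 5), theta = 1,
                         boundaries = data.frame(
                           b = c(0.46, 0.40, 0.42, 0.46),
                           h = c(0.30, 0.50, 0.40, 0.20)),
                         input_gain = 5, weight_gain = 110, bias_gain = 1,
                         synapse = "dynamical", tau_syn = 1, U = 0.5,
                         tau_fac = 1, tau_rec = 10,
                         repeats = 20, T = 20, dt = 0.1, n_draws = 20000,
                         grid_n = 21, base_seed = 1) {
  boundaries <- as.data.frame(boundaries)
  if (ncol(boundaries) == 2L) names(boundaries) <- c("b", "h")
  stopifnot(all(c("b", "h") %in% names(boundaries)), repeats >= 1,
            all(D >= 0), T > 0, dt > 0, grid_n >= 2)
  structure(list(noise_family = noise_family, mode = mode, D = D,
                 theta = theta, boundaries = boundaries,
                 input_gain = input_gain, weight_gain = weight_gain,
                 bias_gain = bias_gain, synapse = synapse, tau_syn = tau_syn,
                 U = U, tau_fac = tau_fac, tau_rec = tau_rec,
                 repeats = repeats, T = T, dt = dt, n_draws = n_draws,
                 grid_n = grid_n, base_seed = base_seed),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat("Noise sweep configuration\n")
  cat(sprintf("  %s %s noise, D = {%s}\n", x$mode, x$noise_family,
              paste(x$D, collapse = ", ")))
  cat(sprintf("  %s synapse, tau_syn = %g ms, gains (%g, %g)\n",
              x$synapse, x$tau_syn, x$input_gain, x$weight_gain))
  cat(sprintf("  %d boundaries, %d repeats, T = %g s, dt = %g ms (%d noise samples per input)\n",
              nrow(x$boundaries), x$repeats, x$T, x$dt,
              as.integer(round(x$T * 1000 / x$dt))))
  invisible(x)
}

#' Read / write a sweep configuration
#'
#' Round-trips a [sweep_config()] through a YAML file.
#'
#' @param path File path.
#' @return `read_sweep_config()` returns a `"sweep_config"`;
#'   `write_sweep_config()` returns `path` invisibly.
#' @export
read_sweep_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$boundaries <- as.data.frame(raw$boundaries)
  do.call(sweep_config, raw)
}

#' @rdname read_sweep_config
#' @param config A [sweep_config()].
#' @export
write_sweep_config <- function(config, path) {
  stopifnot(inherits(config, "sweep_config"))
  out <- unclass(config)
  out$boundaries <- as.list(config$boundaries)
  yaml::write_yaml(out, path)
  invisible(path)
}

sweep_circuit <- function(config) {
  snn_circuit(input_gain = config$input_gain,
              weight_gain = config$weight_gain,
              bias_gain = config$bias_gain, synapse = config$synapse,
              tau_syn = config$tau_syn, U = config$U,
              tau_fac = config$tau_fac, tau_rec = config$tau_rec)
}

sweep_seed <- function(config, i_D, rep) {
  as.integer((config$base_seed + 1000 * (i_D - 1) + (rep - 1)) %% 2147483647)
}

#' Run a noise sweep
#'
#' For every noise level `D` and repeat, simulates the full input grid with
#' a fresh seed, normalizes the surface per run, and evaluates the accuracy
#' of every tracked boundary on that run's surface (all boundaries share
#' the noise realization).  Accuracies are aggregated into means and
#' standard deviations over repeats, and the best tracked boundary per
#' noise level is reported.
#'
#' @param config A [sweep_config()].
#' @param kind `"snn"` (default) or `"ann"` (noise-averaged ReLU circuit).
#' @param keep_surfaces If `TRUE`, store each run's normalized surface
#'   (useful for auditing; memory grows with `length(D) * repeats`).
#' @return An object of class `"xor_sweep"`: a list with the accuracy
#'   array `accuracy[boundary, D, repeat]`, `mean` and `sd` matrices
#'   (`boundary x D`), `best` (data frame of the best boundary per noise
#'   level), the config, and optionally `surfaces`.
#' @export
sweep_noise <- function(config, kind = c("snn", "ann"),
                        keep_surfaces = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  kind <- match.arg(kind)
  grid <- xor_grid(config$grid_n)
  nb <- nrow(config$boundaries)
  nD <- length(config$D)
  circuit <- if (kind == "snn") sweep_circuit(config)
             else ann_circuit(config$input_gain, config$weight_gain,
                              config$bias_gain)
  acc <- array(NA_real_, dim = c(nb, nD, config$repeats),
               dimnames = list(boundary = paste0("(",
                                 config$boundaries$b, ",",
                                 config$boundaries$h, ")"),
                               D = format(config$D), repeat. = NULL))
  surfaces <- if (keep_surfaces) vector("list", nD * config$repeats)
  for (i in seq_len(nD)) {
    spec <- noise_spec(config$noise_family, D = config$D[i],
                       theta = config$theta, mode = config$mode,
                       resample_dt = config$dt)
    for (r in seq_len(config$repeats)) {
      surf <- simulate_surface(circuit, grid, noise = spec, T = config$T,
                               dt = config$dt, n_draws = config$n_draws,
                               seed = sweep_seed(config, i, r))
      if (keep_surfaces) surfaces[[(i - 1) * config$repeats + r]] <- surf
      for (k in seq_len(nb))
        acc[k, i, r] <- xor_accuracy(surf$norm, surf$x0, surf$x1,
                                     config$boundaries$b[k],
                                     config$boundaries$h[k])
    }
  }
  m <- apply(acc, c(1, 2), mean)
  s <- apply(acc, c(1, 2), sd)
  best <- data.frame(D = config$D,
                     boundary = rownames(m)[apply(m, 2, which.max)],
                     accuracy = apply(m, 2, max))
  structure(list(accuracy = acc, mean = m, sd = s, best = best,
                 config = config, kind = kind, surfaces = surfaces),
            class = "xor_sweep")
}

#' @export
print.xor_sweep <- function(x, ...) {
  cat(sprintf("Noise sweep (%s circuit): %s %s noise\n",
              toupper(x$kind), x$config$mode, x$config$noise_family))
  cat("Mean accuracy (boundaries x D):\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' @export
plot.xor_sweep <- function(x, ...) {
  matplot(x$config$D, t(x$mean), type = "b", pch = 16, lty = 1,
          xlab = "noise intensity D", ylab = "mean accuracy", ...)
  legend("bottomright", legend = rownames(x$mean), col = seq_len(nrow(x$mean)),
         lty = 1, pch = 16, cex = 0.8)
  invisible(x)
}

#' Long-format view of a sweep
#'
#' @param x An `"xor_sweep"`.
#' @param ... Unused.
#' @return A data frame with columns `b`, `h`, `D`, `noise_family`, `mode`,
#'   `tau_syn`, `repeat` and `accuracy`, suitable for CSV export.
#' @export
as.data.frame.xor_sweep <- function(x, ...) {
  cfg <- x$config
  nb <- nrow(cfg$boundaries)
  nD <- length(cfg$D)
  idx <- expand.grid(k = seq_len(nb), i = seq_len(nD),
                     r = seq_len(cfg$repeats), KEEP.OUT.ATTRS = FALSE)
  data.frame(b = cfg$boundaries$b[idx$k], h = cfg$boundaries$h[idx$k],
             D = cfg$D[idx$i], noise_family = cfg$noise_family,
             mode = cfg$mode, tau_syn = cfg$tau_syn, repeat. = idx$r,
             accuracy = x$accuracy[cbind(idx$k, idx$i, idx$r)])
}

#' Common versus independent noise, paired
#'
#' Runs the same sweep twice, once with common and once with independent
#' noise, using identical per-run seeds so the curves are paired for
#' variance reduction.
#'
#' @param config A [sweep_config()] (its `mode` field is overridden).
#' @param kind `"snn"` or `"ann"`.
#' @return An object of class `"xor_mode_comparison"`: list with elements
#'   `common`, `independent` (two [sweep_noise()] results) and `gap`
#'   (common minus independent mean accuracy, boundaries x D).
#' @export
compare_modes <- function(config, kind = c("snn", "ann")) {
  stopifnot(inherits(config, "sweep_config"))
  kind <- match.arg(kind)
  cfg_c <- config; cfg_c$mode <- "common"
  cfg_i <- config; cfg_i$mode <- "independent"
  sw_c <- sweep_noise(cfg_c, kind = kind)
  sw_i <- sweep_noise(cfg_i, kind = kind)
  structure(list(common = sw_c, independent = sw_i,
                 gap = sw_c$mean - sw_i$mean),
            class = "xor_mode_comparison")
}

#' @export
print.xor_mode_comparison <- function(x, ...) {
  cat("Common vs independent noise (mean accuracy gap, common - independent):\n")
  print(round(x$gap, 4))
  invisible(x)
}
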