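test_that("the gain search returns a single candidate trivially", {
  gs <- grid_search_gains("ann", input_gains = 6, weight_gains = 111,
                          grid = xor_grid(11))
  expect_equal(gs$best$input_gain, 6)
  expect_equal(gs$best$weight_gain, 111)
  expect_equal(nrow(gs$results), 1)
  expect_error(grid_search_gains("ann", input_gains = numeric(0)),
               "non-empty")
})

test_that("a fixed boundary evaluates without searching", {
  gs <- grid_search_gains("ann", input_gains = c(2, 6), weight_gains = 111,
                          boundary = c(0.46, 0.3), grid = xor_grid(21))
  expect_true(all(gs$results$b == 0.46 & gs$results$h == 0.3))
  # the template's normalized ReLU surface is gain invariant, so both
  # candidates tie and the lexicographically smaller gains win
  expect_equal(gs$best$input_gain, 2)
})

test_that("many interior boundaries score within 1% of the idealized optimum", {
  s <- seq(0, 1, length.out = 201)
  g <- expand.grid(x0 = s, x1 = s)
  fit <- fit_boundary(data.frame(g, norm = abs(g$x0 - g$x1)),
                      b = seq(0.1, 0.9, by = 0.02))
  expect_equal(fit$accuracy, 0.84, tolerance = 0.01)
  expect_gt(summary(fit, tol = 0.01)$n_near, 10)
})

test_that("noise-free sweeps have zero variance across repeats", {
  cfg <- sweep_config(D = 0, repeats = 3, T = 0.5, grid_n = 11,
                      boundaries = data.frame(b = 0.4, h = 0.5))
  sw <- sweep_noise(cfg)
  expect_true(all(sw$sd == 0))
  expect_true(all(sw$accuracy[1, 1, ] == sw$accuracy[1, 1, 1]))
})

test_that("sweeps replay bit-identically from config and seed", {
  cfg <- sweep_config(noise_family = "multiplicative_white", mode = "common",
                      D = c(0, 5), repeats = 2, T = 0.5, grid_n = 11,
                      boundaries = data.frame(b = c(0.3, 0.4),
                                              h = c(0.5, 0.5)),
                      base_seed = 77)
  sw1 <- sweep_noise(cfg)
  sw2 <- sweep_noise(cfg)
  expect_identical(sw1$accuracy, sw2$accuracy)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  # a different base seed changes the noisy surfaces
  cfg2 <- cfg; cfg2$base_seed <- 78
  s1 <- sweep_noise(cfg, keep_surfaces = TRUE)$surfaces[[4]]
  s2 <- sweep_noise(cfg2, keep_surfaces = TRUE)$surfaces[[4]]
  expect_false(identical(s1$raw, s2$raw))
})

test_that("per-cell accuracies equal a recomputation from the stored surfaces", {
  cfg <- sweep_config(noise_family = "multiplicative_white", mode = "common",
                      D = c(0, 5), repeats = 2, T = 0.5, grid_n = 11,
                      boundaries = data.frame(b = c(0.3, 0.46),
                                              h = c(0.5, 0.3)),
                      base_seed = 5)
  sw <- sweep_noise(cfg, keep_surfaces = TRUE)
  for (i in 1:2) for (r in 1:2) {
    surf <- sw$surfaces[[(i - 1) * 2 + r]]
    for (k in 1:2) {
      again <- mean((surf$norm >= cfg$boundaries$h[k]) ==
                      xor(surf$x0 >= cfg$boundaries$b[k],
                          surf$x1 >= cfg$boundaries$b[k]))
      expect_identical(sw$accuracy[k, i, r], again)
    }
  }
})

test_that("the default configuration matches the reference protocol shape", {
  cfg <- sweep_config()
  expect_equal(as.integer(round(cfg$T * 1000 / cfg$dt)), 200000L)
  expect_equal(cfg$repeats, 20)
  expect_equal(cfg$n_draws, 20000)
  expect_equal(cfg$dt, 0.1)
  expect_equal(cfg$T, 20)
})

test_that("configurations round-trip through YAML", {
  cfg <- sweep_config(D = c(0, 1), repeats = 2, T = 1, base_seed = 42,
                      boundaries = data.frame(b = 0.36, h = 0.4))
  f <- tempfile(fileext = ".yaml")
  write_sweep_config(cfg, f)
  cfg2 <- read_sweep_config(f)
  expect_equal(cfg2, cfg)
})

test_that("common and independent modes coincide at D = 0", {
  cfg <- sweep_config(D = 0, repeats = 1, T = 0.5, grid_n = 11,
                      boundaries = data.frame(b = 0.4, h = 0.5))
  cm <- compare_modes(cfg)
  expect_equal(cm$gap, cm$gap * 0)
  expect_identical(cm$common$accuracy, cm$independent$accuracy)
})

test_that("a sub-threshold circuit yields an all-zero rate map", {
  circ <- snn_circuit(input_gain = 1, weight_gain = 110)  # max drive 19 pA
  expect_warning(m <- firing_rate_map(circ, xor_grid(3), T = 0.5), "silent")
  expect_true(all(m == 0))
  expect_equal(dim(m), c(3, 3))
})

test_that("strong common multiplicative noise shifts sensitivity to weaker inputs", {
  circ <- snn_circuit(5, 110, synapse = "dynamical", tau_syn = 20)
  xs <- seq(0, 1, by = 0.05)
  onset <- function(D) {
    ns <- if (D > 0) noise_spec("multiplicative_white", D = D,
                                mode = "common") else NULL
    r <- vapply(xs, function(x)
      run_snn(circ, x, 0, noise = ns, T = 1, seed = 5)$rates[[5]], numeric(1))
    xs[which(r > 1)[1]]
  }
  expect_lt(onset(5), onset(0))
})

test_that("dynamical synapses with long tau_syn keep contrast under strong noise", {
  spn <- noise_spec("multiplicative_white", D = 5, mode = "common")
  v20 <- simulate_surface(snn_circuit(5, 110, synapse = "dynamical",
                                      tau_syn = 20),
                          xor_grid(21), noise = spn, T = 2, seed = 42)
  vst <- simulate_surface(snn_circuit(5, 110, synapse = "static",
                                      tau_syn = 1),
                          xor_grid(21), noise = spn, T = 2, seed = 42)
  expect_gt(var(v20$norm), var(vst$norm))
})

test_that("the common-independent gap grows with D at short tau_syn and stays small at long tau_syn for moderate noise", {
  b <- data.frame(b = 0.36, h = 0.4)
  cfg1 <- sweep_config(noise_family = "multiplicative_white", D = c(1, 2, 5),
                       tau_syn = 1, input_gain = 5, weight_gain = 110,
                       boundaries = b, repeats = 4, T = 2, base_seed = 21)
  cm1 <- compare_modes(cfg1)
  expect_true(all(diff(abs(as.numeric(cm1$gap))) > 0))
  cfg20 <- sweep_config(noise_family = "multiplicative_white", D = c(1, 2),
                        tau_syn = 20, input_gain = 5, weight_gain = 25,
                        boundaries = b, repeats = 4, T = 2, base_seed = 21)
  cm20 <- compare_modes(cfg20)
  expect_true(all(abs(cm20$gap) < 0.05))
})
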