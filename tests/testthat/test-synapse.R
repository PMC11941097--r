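# independent oracle for the short-term plasticity dynamics: integrate the
# three-state ODE system between spikes with deSolve (no closed forms) and
# apply the spike map, returning the release fraction at each spike
tm_release_oracle <- function(params, times) {
  deriv <- function(t, s, p) {
    list(c(-s[["u"]] / p$tau_fac,
           (1 - s[["x"]] - s[["y"]]) / p$tau_rec,
           -s[["y"]] / p$tau_syn))
  }
  s <- c(u = 0, x = 1, y = 0)
  rel <- numeric(length(times))
  for (i in seq_along(times)) {
    if (i > 1 && times[i] > times[i - 1]) {
      sol <- deSolve::ode(s, c(0, times[i] - times[i - 1]), deriv, params,
                          rtol = 1e-10, atol = 1e-12)
      s <- setNames(sol[2, c("u", "x", "y")], c("u", "x", "y"))
    }
    u <- s[["u"]] + params$U * (1 - s[["u"]])
    r <- u * s[["x"]]
    s <- c(u = u, x = s[["x"]] - r, y = s[["y"]] + r)
    rel[i] <- r
  }
  rel
}

test_that("the PSC decays exponentially and dt = 0 is the identity", {
  p <- synapse_params(weight = 100, tau_syn = 1)
  s <- synapse_state(I_psc = 100)
  expect_equal(decay_psc(s, p, 1)$I_psc, 100 / exp(1))
  expect_equal(decay_psc(s, p, 0), s)
  # recovery limit: depleted resources return to 1 after a long pause
  s2 <- decay_psc(synapse_state(u = 0.3, x = 0.5), p, 1e5)
  expect_equal(s2$x, 1, tolerance = 1e-12)
  expect_equal(s2$u, 0, tolerance = 1e-12)
})

test_that("a spike from rest releases the baseline utilization", {
  p <- synapse_params(weight = 80, U = 0.5)
  s <- on_presynaptic_spike(synapse_state(), p)
  expect_equal(s$u, 0.5)
  expect_equal(attr(s, "release"), 0.5)
  expect_equal(s$I_psc, 0.5 * 80)
  expect_equal(s$x, 0.5)
})

test_that("a static synapse increments the PSC by its full weight every spike", {
  p <- synapse_params(weight = -30, kind = "static")
  s <- synapse_state()
  for (i in 1:3) s <- on_presynaptic_spike(s, p)
  expect_equal(s$I_psc, -90)
  expect_equal(s$x, 1)
  expect_equal(synapse_release_train(c(0, 1, 2), p), rep(1, 3))
})

test_that("release fractions along a train match the ODE oracle", {
  p <- synapse_params(U = 0.5, tau_fac = 1, tau_rec = 10, tau_syn = 1)
  # 100 Hz regular train: steady-state depression
  times <- seq(0, by = 10, length.out = 60)
  rel <- synapse_release_train(times, p)
  oracle <- tm_release_oracle(p, times)
  expect_equal(rel, oracle, tolerance = 1e-6)
  # steady state reached: last two releases agree to 1e-6
  expect_lt(abs(rel[60] - rel[59]), 1e-6)
  # irregular train, facilitation-dominated parameters
  p2 <- synapse_params(U = 0.2, tau_fac = 50, tau_rec = 5, tau_syn = 2)
  times2 <- cumsum(c(0, 3, 1, 8, 2, 40, 1, 1))
  expect_equal(synapse_release_train(times2, p2),
               tm_release_oracle(p2, times2), tolerance = 1e-6)
})

test_that("sustained fast drive depresses release; long pauses restore it", {
  p <- synapse_params()
  rel <- synapse_release_train(seq(0, by = 1, length.out = 20), p)
  expect_equal(rel[1], 0.5)
  expect_lt(rel[2], rel[1])
  expect_lt(rel[20], rel[1])
  # all later releases stay below the first, and convergence sets in
  expect_true(all(rel[-1] < rel[1]))
  expect_lt(abs(rel[20] - rel[19]), 1e-3)
  # with negligible facilitation and a fast-draining active pool the
  # depression map reduces to the two-state form and is strictly monotone
  pd <- synapse_params(U = 0.5, tau_fac = 1e-3, tau_rec = 10, tau_syn = 0.1)
  rd <- synapse_release_train(seq(0, by = 1, length.out = 20), pd)
  expect_true(all(diff(rd) <= 1e-12))
  # two spikes ten recovery periods apart release equally
  rel2 <- synapse_release_train(c(0, 10 * p$tau_rec), p)
  expect_lt(abs(rel2[2] - rel2[1]), 1e-4)
  expect_error(synapse_release_train(c(5, 1), p), "sorted")
  expect_equal(synapse_release_train(0, p), 0.5)
})

test_that("resource pools stay in [0, 1] and sum to one", {
  p <- synapse_params(weight = 2, U = 0.7, tau_fac = 30, tau_rec = 8,
                      tau_syn = 3)
  set.seed(42)
  for (rep in 1:10) {
    s <- synapse_state()
    tt <- cumsum(rexp(50, rate = 1 / 5))
    t_prev <- 0
    for (t in tt) {
      s <- decay_psc(s, p, t - t_prev)
      if (runif(1) < 0.8) s <- on_presynaptic_spike(s, p)
      t_prev <- t
      y <- s$I_psc / p$weight
      expect_true(s$x >= 0 && s$x <= 1)
      expect_true(y >= -1e-9 && y <= 1 + 1e-9)
      expect_true(s$u >= 0 && s$u <= 1)
      expect_true(1 - s$x - y >= -1e-9 && 1 - s$x - y <= 1 + 1e-9)
    }
  }
})

test_that("the static synapse is the fast-recovery, full-utilization limit", {
  # U = 1, tau_rec -> 0, tau_fac -> 0; spikes separated by >> tau_syn so the
  # active pool has drained before the next release
  w <- 55
  dyn <- synapse_params(weight = w, U = 1, tau_fac = 1e-9, tau_rec = 1e-9,
                        tau_syn = 1)
  sta <- synapse_params(weight = w, kind = "static", tau_syn = 1)
  times <- seq(0, by = 20, length.out = 10)
  sd_ <- synapse_state(); ss <- synapse_state()
  t_prev <- 0
  for (t in times) {
    sd_ <- on_presynaptic_spike(decay_psc(sd_, dyn, t - t_prev), dyn)
    ss <- on_presynaptic_spike(decay_psc(ss, sta, t - t_prev), sta)
    expect_equal(sd_$I_psc, ss$I_psc, tolerance = 1e-6)
    t_prev <- t
  }
})

test_that("the PSC time integral equals |weight * release| * tau_syn", {
  for (tau in c(1, 20)) {
    p <- synapse_params(weight = 100, tau_syn = tau)
    s <- on_presynaptic_spike(synapse_state(), p)
    I0 <- s$I_psc
    dt <- 0.01
    n <- as.integer(40 * tau / dt)
    vals <- numeric(n + 1)
    vals[1] <- s$I_psc
    for (i in seq_len(n)) {
      s <- decay_psc(s, p, dt)
      vals[i + 1] <- s$I_psc
    }
    integral <- sum((vals[-1] + vals[-(n + 1)]) / 2) * dt
    expect_equal(integral, I0 * tau, tolerance = 1e-3)
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(synapse_params(tau_syn = 0), "tau_syn")
  expect_error(synapse_params(U = 1.5), "U")
  expect_error(synapse_params(tau_rec = -1), "tau_rec")
  expect_error(synapse_state(u = 2))
})
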