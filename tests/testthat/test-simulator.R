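test_that("uncoupled limit-cycle amplitude settles at sqrt(a)", {
  net <- toy_network(matrix(0, 3, 3))
  par0 <- toy_params(f = rep(0.05, 3), a = rep(0.25, 3))
  cfg <- sim_config(
    duration = 400, transient = 300, noise_amplitude = 0,
    seed = 7, model_kind = "limit_cycle"
  )
  run <- simulate_network(net, par0, C = 0, tau = 0, cfg)
  radius <- sqrt(run$observable^2 + run$imag^2)
  expect_true(all(abs(tail(radius, 100) - 0.5) < 1e-3))
  # oscillation period 1/f = 20 s within one step: count zero crossings
  x <- run$observable[, 1]
  ups <- which(diff(sign(x)) > 0)
  periods <- diff(ups) * 0.06
  expect_true(all(abs(periods - 20) <= 0.06 + 1e-9))
})

test_that("uncoupled phase trajectories match the analytic solution", {
  net <- toy_network(matrix(0, 2, 2))
  par0 <- toy_params(f = c(0.03, 0.07))
  cfg <- sim_config(
    duration = 99.96, transient = 0, noise_amplitude = 0,
    seed = 3, model_kind = "phase"
  )
  run <- simulate_network(net, par0, C = 0, tau = 0, cfg)
  set.seed(3)
  phi0 <- 2 * pi * runif(2)
  tvec <- seq_len(nrow(run$observable)) * 0.06
  for (j in 1:2) {
    expect_lt(
      max(abs(run$observable[, j] - sin(phi0[j] + 2 * pi * par0$f[j] * tvec))),
      1e-6
    )
  }
})

test_that("two identical phase oscillators synchronize under coupling", {
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  net <- toy_network(w)
  par0 <- toy_params(f = c(0.05, 0.05))
  cfg <- sim_config(
    duration = 300, transient = 200, noise_amplitude = 0,
    seed = 11, model_kind = "phase"
  )
  run <- simulate_network(net, par0, C = 0.4, tau = 0, cfg)
  # after the transient the phase difference has decayed: signals equal
  expect_lt(max(abs(run$observable[, 1] - run$observable[, 2])), 1e-4)
})

test_that("the two-oscillator locking threshold sits at 2 pi df = C w", {
  # each oscillator sees (C/N) w sin(+-Delta) with N = 2 and w = 1 on both
  # links, so the phase difference obeys Delta' = 2 pi df - C sin(Delta):
  # locking iff C >= 2 pi df
  df <- 0.004
  C_star <- 2 * pi * df
  net <- toy_network(matrix(c(0, 1, 1, 0), 2, 2))
  par0 <- toy_params(f = c(0.05, 0.05 + df))
  cfg <- sim_config(
    duration = 3000, transient = 500, noise_amplitude = 0,
    seed = 2, model_kind = "phase"
  )
  drift_rate <- function(C) {
    run <- simulate_network(net, par0, C = C, tau = 0, cfg)
    # frequency difference of the retained observables via zero crossings
    f_obs <- apply(run$observable, 2, function(x) {
      length(which(diff(sign(x)) > 0)) / (nrow(run$observable) * 0.06)
    })
    abs(f_obs[2] - f_obs[1])
  }
  # below threshold the beat frequency is df * sqrt(1 - 0.8^2) = 0.6 df
  expect_lt(drift_rate(C_star * 1.2), 0.0006) # locked above threshold
  expect_gt(drift_rate(C_star * 0.8), 0.0015) # drifting below threshold
})

test_that("trajectories are bit-identical under the same seed", {
  p <- make_parcellation_hierarchy(8, 8, seed = 1)[[1]]
  sc <- make_structural_connectome(p, seed = 2)
  net <- toy_network(normalize_weights(sc$counts), sc$lengths)
  par0 <- toy_params(f = seq(0.02, 0.08, length.out = 8))
  for (mk in c("phase", "limit_cycle")) {
    cfg <- sim_config(duration = 60, transient = 10, seed = 5, model_kind = mk)
    r1 <- simulate_network(net, par0, 0.4, 3, cfg)
    r2 <- simulate_network(net, par0, 0.4, 3, cfg)
    expect_identical(r1$observable, r2$observable)
  }
})

test_that("halving the step shrinks the error like a second-order scheme", {
  # uncoupled Hopf relaxation toward the limit cycle is the nonlinear
  # closed form; compare both step sizes against a much finer reference
  net <- toy_network(matrix(0, 1, 1))
  par0 <- toy_params(f = 0.05, a = 0.36)
  run_at <- function(dt) {
    cfg <- sim_config(
      duration = 48, transient = 0, noise_amplitude = 0,
      dt = dt, seed = 9, model_kind = "limit_cycle"
    )
    simulate_network(net, par0, 0, 0, cfg)
  }
  ref <- run_at(0.0075)
  r1 <- run_at(0.06)
  r2 <- run_at(0.03)
  at <- function(run, tsec) {
    run$observable[round(tsec / run$dt), 1]
  }
  e1 <- abs(at(r1, 48) - at(ref, 48))
  e2 <- abs(at(r2, 48) - at(ref, 48))
  expect_lt(e2, e1 / 2.5) # consistent with order ~2 deterministic accuracy
})

test_that("sFC matches a brute-force pairwise Pearson oracle", {
  set.seed(21)
  x <- matrix(rnorm(200 * 5), 200, 5)
  run <- structure(
    list(observable = x, model_kind = "phase", dt = 0.06),
    class = "sim_run"
  )
  fc <- compute_sfc(run)
  for (i in 1:5) {
    for (j in 1:5) {
      expect_lt(abs(fc[i, j] - pearson_brute(x[, i], x[, j])), 1e-12)
    }
  }
  expect_equal(diag(fc), rep(1, 5))
})

test_that("sFC is invariant to per-region affine rescaling and flips sign", {
  set.seed(22)
  x <- matrix(rnorm(300 * 4), 300, 4)
  fc <- compute_sfc(x)
  scaled <- sweep(x, 2, c(2, 0.5, 7, 1.3), "*") +
    matrix(rep(c(-3, 0, 5, 1), each = 300), 300, 4)
  expect_equal(compute_sfc(scaled), fc, tolerance = 1e-12)
  flipped <- x
  flipped[, 2] <- -flipped[, 2]
  fc_f <- compute_sfc(flipped)
  expect_equal(fc_f[2, -2], -fc[2, -2], tolerance = 1e-12)
})

test_that("identical and constant signals are handled as specified", {
  x <- matrix(rnorm(100), 100, 1)[, c(1, 1, 1)]
  expect_true(all(compute_sfc(x) == 1))
  xc <- cbind(rnorm(100), rep(1, 100))
  expect_error(compute_sfc(xc), "region")
})

test_that("strong coupling of identical oscillators synchronizes the network", {
  p <- make_parcellation_hierarchy(10, 10, seed = 3)[[1]]
  sc <- make_structural_connectome(p, seed = 4)
  net <- toy_network(normalize_weights(sc$counts), matrix(0, 10, 10))
  par0 <- toy_params(f = rep(0.05, 10))
  cfg <- sim_config(
    duration = 700, transient = 500, noise_amplitude = 0,
    seed = 6, model_kind = "phase"
  )
  run <- simulate_network(net, par0, C = 5, tau = 0, cfg)
  fc <- compute_sfc(run)
  expect_true(all(fc[upper.tri(fc)] > 1 - 1e-2))
})

test_that("retained length equals (duration - transient) / dt", {
  net <- toy_network(matrix(0, 2, 2))
  par0 <- toy_params(f = c(0.03, 0.05))
  cfg <- sim_config(duration = 60, transient = 12, seed = 1)
  run <- simulate_network(net, par0, 0, 0, cfg)
  expect_equal(nrow(run$observable), (60 - 12) / 0.06)
  expect_true(all(abs(run$observable) <= 1))
})
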