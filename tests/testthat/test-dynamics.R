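test_that("natural frequency draws have the requested distribution", {
  w0 <- draw_natural_frequencies(7, mean_freq = 10, freq_sd = 0, seed = 1)
  expect_equal(as.numeric(w0), rep(2 * pi * 10 / 1000, 7))
  w <- draw_natural_frequencies(1000, mean_freq = 35, freq_sd = 0.1, seed = 2)
  nu <- attr(w, "nu")
  expect_lt(abs(mean(nu) - 35), 3 * 0.1 / sqrt(1000))
  expect_identical(as.numeric(w), as.numeric(2 * pi * nu / 1000))
  expect_identical(w, draw_natural_frequencies(1000, 35, 0.1, seed = 2))
  expect_error(draw_natural_frequencies(5, -1), "positive")
})

test_that("config validation enforces the sampling and window constraints", {
  expect_error(sim_config(mean_freq = 300), "record_dt")
  expect_error(sim_config(mean_freq = 10, t_record = 0), "positive")
  expect_error(sim_config(mean_freq = 10, n_realizations = 0), ">= 1")
  expect_error(sim_config(mean_freq = 10, min_step = 2), "min_step")
  cfg <- sim_config(mean_freq = 51)
  expect_equal(cfg$n_realizations, 200L)
  expect_equal(cfg$t_transient, 7)
  expect_equal(cfg$t_record, 12)
})

test_that("an uncoupled noise-free oscillator advances linearly at omega", {
  con <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  cfg <- quick_config(mean_freq = 10, t_transient = 1, t_record = 2)
  tr <- simulate_phases(con, uniform_delays(con, 0), cfg)
  u <- unwrap_phases(tr)
  drift <- u[1, ncol(u)] - u[1, 1]
  expect_lt(abs(drift - 2 * pi * 10 / 1000 * 2000), 1e-6)
})

test_that("with zero coupling every unwrapped phase is linear in time", {
  con <- toy_connectome(n = 3)
  cfg <- quick_config(mean_freq = 8, freq_sd = 0.5, coupling = 0,
                      t_transient = 1, t_record = 1, seed = 4)
  tr <- simulate_phases(con, distance_delays(con, 5), cfg)
  u <- unwrap_phases(tr)
  for (i in 1:3) {
    fit <- stats::lm(u[i, ] ~ tr$times)
    expect_lt(abs(unname(stats::coef(fit)[2]) - tr$omega[i]), 1e-9)
    expect_lt(max(abs(stats::residuals(fit))), 1e-6)
  }
})

test_that("delay-free simulation matches a fixed-step RK4 reference", {
  n <- 5
  con <- synthetic_connectome(n = n, n_modules = 1, weight_decades = 1,
                              seed = 9)
  cfg <- quick_config(mean_freq = 10, freq_sd = 0.2, coupling = 0.25,
                      t_transient = 1, t_record = 1, seed = 11)
  tr <- simulate_phases(con, uniform_delays(con, 0), cfg)

  # reproduce the realization's own draws, then integrate classic Kuramoto
  omega <- tr$omega
  theta0 <- local({
    set.seed(11)
    stats::rnorm(n, cfg$mean_freq, cfg$freq_sd)
    stats::runif(n, 0, 2 * pi)
  })
  K <- cfg$coupling * con$weights
  rhs <- function(th) {
    omega + rowSums(K * sin(outer(th, th, function(a, b) b - a)))
  }
  dt <- 0.05
  th <- theta0
  ref <- matrix(NA_real_, n, length(tr$times))
  steps_per_ms <- round(1 / dt)
  idx <- 0
  for (t_ms in seq_len(2000)) {
    for (s in seq_len(steps_per_ms)) {
      k1 <- rhs(th); k2 <- rhs(th + dt / 2 * k1)
      k3 <- rhs(th + dt / 2 * k2); k4 <- rhs(th + dt * k3)
      th <- th + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (t_ms >= 1000) { idx <- idx + 1; ref[, idx] <- th }
  }
  u <- unwrap_phases(tr)
  off <- u[, 1] - ref[, 1]      # unwrapping offset is a multiple of 2 pi
  expect_lt(max(abs(off - 2 * pi * round(off / (2 * pi)))), 1e-4)
  err <- (u - ref) - off
  expect_lt(max(abs(err)), 1e-4)
})

test_that("two weakly coupled identical oscillators lock as the oracle predicts", {
  pc <- pair_connectome(1, 25)
  dl <- uniform_delays(pc, 5)
  # K -> 0+ regime: boundary shift ~ 1.6 Hz, states as the analytic limit
  cfg_in <- quick_config(mean_freq = 10, coupling = 0.01, t_transient = 7,
                         t_record = 3, seed = 5)
  s_in <- correlation_index(simulate_phases(pc, dl, cfg_in))[1, 2]
  expect_gt(s_in, 0.9)
  expect_equal(two_node_locked_state(0.01, 5, 10)$state, "in_phase")

  cfg_anti <- quick_config(mean_freq = 70, coupling = 0.01, t_transient = 7,
                           t_record = 3, record_dt = 0.5, seed = 6)
  s_anti <- correlation_index(simulate_phases(pc, dl, cfg_anti))[1, 2]
  expect_lt(s_anti, -0.9)
  expect_equal(two_node_locked_state(0.01, 5, 70)$state, "anti_phase")
})

test_that("noise variance grows linearly in time with slope noise_sd^2", {
  con <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  cfg <- quick_config(mean_freq = 5, noise_sd = 0.05, t_transient = 0.1,
                      t_record = 1, n_realizations = 100, seed = 13)
  ens <- run_ensemble(con, uniform_delays(con, 0), cfg)
  # pooled variance of phase increments over disjoint 100 ms blocks
  block <- 100
  incs <- unlist(lapply(ens, function(tr) {
    u <- unwrap_phases(tr)[1, ]
    k <- seq(1, length(u), by = block)
    diff(u[k]) - tr$omega[1] * block
  }))
  expect_equal(stats::var(incs), 0.05^2 * block, tolerance = 0.2)
})

test_that("ensembles are reproducible and realizations are distinct", {
  con <- toy_connectome()
  cfg <- quick_config(mean_freq = 10, freq_sd = 0.1, noise_sd = 0.05,
                      t_transient = 1, t_record = 0.2, n_realizations = 2,
                      seed = 21)
  e1 <- run_ensemble(con, distance_delays(con, 5), cfg)
  e2 <- run_ensemble(con, distance_delays(con, 5), cfg)
  expect_identical(e1[[1]]$phases, e2[[1]]$phases)
  expect_identical(e1[[2]]$phases, e2[[2]]$phases)
  expect_false(identical(e1[[1]]$phases, e1[[2]]$phases))
  expect_false(identical(e1[[1]]$omega, e1[[2]]$omega))

  e3 <- simulate(con, nsim = 2, seed = 21, delays = distance_delays(con, 5),
                 config = cfg)
  expect_identical(e3[[1]]$phases, e1[[1]]$phases)
})

test_that("invalid delay setups are rejected", {
  con <- toy_connectome()
  cfg <- quick_config(mean_freq = 10, t_transient = 1, t_record = 0.2)
  bad <- matrix(2000, 3, 3); diag(bad) <- 0
  expect_error(simulate_phases(con, bad, cfg), "transient")
  wrong <- uniform_delays(toy_connectome(n = 4), 1)
  expect_error(simulate_phases(con, wrong, cfg), "conform")
})
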