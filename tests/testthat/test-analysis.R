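test_that("graph density reproduces the worked examples", {
  expect_equal(round(graph_density(29, 536, directed = TRUE)), 66)
  expect_equal(graph_density(29, 536, TRUE), 100 * 536 / 812)
  expect_equal(graph_density(29, 0, TRUE), 0)
  expect_equal(graph_density(29, 812, TRUE), 100)
  expect_equal(graph_density(4, 6, FALSE), 100)
  expect_error(graph_density(29, 813, TRUE), "must lie in")
})

test_that("similarity distance is zero at identity and matches hand values", {
  con <- pair_connectome(c(0.5, 0.5), 30)
  sig <- con$weights; diag(sig) <- 1
  expect_equal(fc_similarity(fc_matrix(sig), con), 0)

  # two masked pairs with differences {1, -1}: sqrt(2) / 2
  w <- matrix(0, 3, 3)
  w[1, 3] <- w[3, 1] <- 1
  w[1, 2] <- w[2, 1] <- 1e-12
  d <- matrix(10, 3, 3); diag(d) <- 0
  con2 <- connectome(w, d, weight_threshold = 0)
  sg <- matrix(0, 3, 3); diag(sg) <- 1
  sg[1, 2] <- sg[2, 1] <- 1
  expect_equal(fc_similarity(fc_matrix(sg), con2), sqrt(2) / 2,
               tolerance = 1e-9)
  expect_error(fc_similarity(fc_matrix(diag(3)),
                             connectome(matrix(0, 3, 3), d)), "empty")
})

test_that("similarity distance is a metric on the all-pairs mask", {
  rand_sym <- function() {
    m <- matrix(stats::runif(16), 4, 4)
    m <- (m + t(m)) / 2; diag(m) <- 0
    m
  }
  d <- matrix(10, 4, 4); diag(d) <- 0
  dist_fun <- function(a, b) {
    con <- connectome(b, d, weight_threshold = 0)
    sig <- a; diag(sig) <- 1
    fc_similarity(fc_matrix(sig), con, pairs = "all")
  }
  set.seed(99)
  for (rep in 1:20) {
    a <- rand_sym(); b <- rand_sym(); c <- rand_sym()
    expect_equal(dist_fun(a, b), dist_fun(b, a), tolerance = 1e-12)
    expect_gte(dist_fun(a, b) + dist_fun(b, c) - dist_fun(a, c), -1e-12)
    expect_equal(dist_fun(a, a), 0)
    if (max(abs(a - b)) > 0) expect_gt(dist_fun(a, b), 0)
  }
})

test_that("binning by weight and distance summarizes connected pairs", {
  con <- pair_connectome(c(0.9, 0.9, 0.9), c(10, 20, 50))
  sig <- diag(6)
  sig[1, 2] <- sig[2, 1] <- 1       # d = 10 < 30
  sig[3, 4] <- sig[4, 3] <- 1       # d = 20 < 30
  sig[5, 6] <- sig[6, 5] <- -1      # d = 50
  fc <- fc_matrix(sig, mean_freq = 11)

  # one wide bin holds every pair: bin mean equals the global mean
  b1 <- bin_correlation(fc, con, by = "weight", width = 2, centers = 1)
  expect_equal(b1$mean_sigma, mean(c(1, 1, -1)))
  expect_equal(b1$n_pairs, 3L)
  expect_equal(b1$mean_freq, 11)

  # piecewise-constant sigma splits cleanly across distance bins
  b2 <- bin_correlation(fc, con, by = "distance", width = 30,
                        centers = c(15, 45))
  expect_equal(b2$mean_sigma, c(1, -1))
  expect_true(all(b2$ci_low <= b2$mean_sigma & b2$mean_sigma <= b2$ci_high))

  # default widths follow the binning convention (0.05 / 16 mm)
  b3 <- bin_correlation(fc, con, by = "weight")
  expect_equal(attr(b3, "width"), 0.05)
  b4 <- bin_correlation(fc, con, by = "distance")
  expect_equal(attr(b4, "width"), 16)
  expect_equal(sum(b4$n_pairs), 3L)

  empty <- connectome(matrix(0, 6, 6), con$distances)
  expect_error(bin_correlation(fc, empty), "no connected pairs")
})

test_that("the locking oracle reproduces the analytic limits", {
  # no delay: classic Kuramoto pair, in-phase for any frequency
  for (nu in c(3, 23, 70))
    expect_equal(two_node_locked_state(0.25, 0, nu)$state, "in_phase")

  # K -> 0+: classification by cos(2 pi nu tau)
  st1 <- two_node_locked_state(1e-4, 5, 10)
  expect_equal(st1$state, "in_phase")
  expect_equal(st1$roots$Omega_tau[1], 2 * pi * 10 / 1000 * 5,
               tolerance = 1e-3)
  st2 <- two_node_locked_state(1e-4, 5, 70)
  expect_equal(st2$state, "anti_phase")

  # boundary scaling: state flips near nu = 250 / tau
  expect_equal(two_node_locked_state(1e-4, 10, 24)$state, "in_phase")
  expect_equal(two_node_locked_state(1e-4, 10, 26)$state, "anti_phase")

  # strong-coupling long-delay regime admits bistability
  st3 <- two_node_locked_state(0.25, 15, 40)
  expect_true(st3$state %in% c("bistable", "in_phase", "anti_phase"))
  expect_true(all(c("branch", "Omega", "Omega_tau", "stable") %in%
                  names(st3$roots)))
  expect_error(two_node_locked_state(-1, 5, 10), ">= 0")
  expect_error(two_node_locked_state(0.1, 5, -1), "positive")
})

test_that("zero-crossing detection interpolates between grid points", {
  expect_equal(first_zero_crossing(c(1, 2, 3), c(1, 1, 1)), NA_real_)
  expect_equal(first_zero_crossing(c(1, 2, 3), c(-1, 1, -1)), 1)
  expect_equal(first_zero_crossing(c(0, 10), c(1, -1)), 5)
  expect_equal(first_zero_crossing(c(0, 10, 20), c(1, 0.5, -0.5)), 15)
})

test_that("a single-frequency sweep agrees with a direct ensemble run", {
  con <- toy_connectome()
  cfg <- quick_config(mean_freq = 10, noise_sd = 0.05, t_transient = 1,
                      t_record = 0.3, n_realizations = 2, seed = 31)
  sw <- frequency_sweep(con, distance_delays(con, 5), cfg, freqs = 10)
  cfg2 <- cfg
  cfg2$seed <- local({
    set.seed(31); sample.int(.Machine$integer.max, 1)
  })
  class(cfg2) <- "sim_config"
  fc <- ensemble_fc(run_ensemble(con, distance_delays(con, 5), cfg2))
  expect_equal(unclass(sw$fc[[1]]), unclass(fc), tolerance = 1e-12)
  expect_equal(sw$summary$similarity,
               fc_similarity(fc, con), tolerance = 1e-12)
  expect_equal(nrow(sw$summary), 1L)
})
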