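test_that("constructor validates matrices and counts edges", {
  con <- toy_connectome()
  expect_s3_class(con, "connectome")
  expect_equal(con$n, 3)
  expect_equal(n_edges(con), 3)            # undirected pairs
  expect_equal(sum(con$weights > 0), 6)    # six directed entries

  w <- matrix(0.5, 3, 3); diag(w) <- 0
  d <- matrix(10, 3, 3); diag(d) <- 0
  expect_error(connectome(w[, 1:2], d), "square")
  expect_error(connectome(w, d[1:2, 1:2]), "dimension")
  expect_error(connectome(-w, d), "negative")
  da <- d; da[1, 2] <- 20
  expect_error(connectome(w, da), "asymmetric")
  d0 <- d; d0[1, 2] <- d0[2, 1] <- 0
  expect_error(connectome(w, d0), "positive distance")
  wa <- w; wa[1, 2] <- 0.9
  expect_error(connectome(wa, d), "symmetric")
  expect_silent(connectome(wa, d, directed = TRUE))
})

test_that("weights are rescaled to max 1 and sub-threshold weights dropped", {
  w <- matrix(c(0, 3, 3, 0), 2, 2)
  d <- matrix(c(0, 10, 10, 0), 2, 2)
  con <- connectome(w, d)
  expect_equal(max(con$weights), 1)
  expect_equal(attr(con, "scale_factor"), 3)

  w2 <- matrix(c(0, 1e-6, 1e-6, 0), 2, 2)
  con2 <- connectome(w2, d)
  expect_equal(n_edges(con2), 0)
  con3 <- connectome(w2, d, weight_threshold = 0)
  expect_equal(n_edges(con3), 1)
})

test_that("write/read round trip reproduces the matrices", {
  con <- synthetic_connectome(n = 12, n_modules = 2, seed = 5)
  wf <- tempfile(fileext = ".tsv"); df <- tempfile(fileext = ".tsv")
  write_connectome(con, wf, df)
  back <- read_connectome(wf, df)
  expect_equal(back$weights, con$weights, tolerance = 1e-12)
  expect_equal(back$distances, con$distances, tolerance = 1e-12)
  expect_error(read_connectome(wf, tempfile()), "not found")
})

test_that("binarize maps positive weights to one and is idempotent", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.003
  w[2, 3] <- w[3, 2] <- 0.8
  d <- matrix(10, 3, 3); diag(d) <- 0
  con <- connectome(w, d, weight_threshold = 0)
  b <- binarize(con)
  expect_setequal(unique(as.vector(b$weights)), c(0, 1))
  expect_equal(b$weights > 0, con$weights > 0)
  expect_equal(b$distances, con$distances)
  expect_equal(binarize(b)$weights, b$weights)
  empty <- connectome(matrix(0, 3, 3), d)
  expect_equal(sum(binarize(empty)$weights), 0)
})

test_that("distance delays follow tau = d / speed in ms", {
  con <- pair_connectome(c(1, 1), c(25, 160))
  dl <- distance_delays(con, speed = 5)
  expect_equal(dl[1, 2], 5)    # 25 mm / 5 m/s
  expect_equal(dl[3, 4], 32)   # 160 mm / 5 m/s
  expect_equal(dl[1, 3], 0)    # non-edge
  expect_error(distance_delays(con, speed = 0), "positive")
})

test_that("uniform delays cover edges only", {
  con <- toy_connectome()
  dl <- uniform_delays(con, 10)
  expect_equal(sort(unique(dl[upper.tri(dl)])), c(10))
  expect_equal(diag(dl), rep(0, 3))
  dl0 <- uniform_delays(con, 0)
  expect_true(all(dl0 == 0))
  expect_error(uniform_delays(con, -1), "non-negative")
})

test_that("synthetic generator matches the target structural statistics", {
  con <- synthetic_connectome(n = 66, n_modules = 6, weight_decades = 5,
                              decay_length = 40, seed = 1)
  s <- summary(con)
  expect_gte(s$weight_decades, 4)
  expect_lt(s$weight_distance_cor, 0)
  expect_lte(max(con$distances), 160 + 1e-9)
  expect_setequal(unique(con$hemisphere), c("L", "R"))
  expect_equal(length(unique(con$module)), 6)

  # two nodes: renormalization forces a single edge of weight 1
  con2 <- synthetic_connectome(n = 2, n_modules = 1, seed = 3)
  expect_equal(n_edges(con2), 1)
  expect_equal(max(con2$weights), 1)

  # seeded determinism
  a <- synthetic_connectome(n = 20, n_modules = 2, seed = 7)
  b <- synthetic_connectome(n = 20, n_modules = 2, seed = 7)
  expect_identical(a$weights, b$weights)
  expect_identical(a$distances, b$distances)
})

test_that("generated connectomes satisfy the invariants for many seeds", {
  for (seed in 1:50) {
    con <- synthetic_connectome(n = 66, n_modules = 6, seed = seed)
    w <- con$weights; d <- con$distances
    expect_true(all(diag(w) == 0))
    expect_identical(w, t(w))
    expect_identical(d, t(d))
    expect_true(all(w >= 0) && max(w) <= 1)
    expect_true(all(d >= 0) && all(diag(d) == 0))
    expect_true(all(d[w > 0] > 0))
    s <- summary(con)
    expect_lt(s$weight_distance_cor, 0)  # decay length 40 mm <= 60 mm
  }
})
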