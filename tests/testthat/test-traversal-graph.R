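test_that("bin indexing follows the half-open grid with a closed top bin", {
  g <- bin_grid()
  expect_equal(g$n_bins, 100L)
  expect_equal(bin_index(0.05, g), 0L)
  expect_equal(bin_index(0.1, g), 1L)
  expect_equal(bin_index(10.0, g), 99L)
  expect_equal(bin_index(c(0, 9.9, 5.55), g), c(0L, 99L, 55L))
  expect_error(bin_index(10.5, g), class = "velozone_validation_error")
  expect_error(bin_index(-0.1, g), class = "velozone_validation_error")
  expect_error(bin_grid(0, 10, 0.3), class = "velozone_validation_error")
})

test_that("traversal counts record adjacent-sample bin transitions", {
  tr <- velocity_trace(times = 0:3 / 10, velocities = c(0.05, 0.17, 0.33, 0.29))
  counts <- traversal_matrix(tr)$counts
  expect_equal(sum(counts), 3)
  expect_equal(counts[1, 2], 1)  # bin 0 -> 1
  expect_equal(counts[2, 4], 1)  # bin 1 -> 3
  expect_equal(counts[4, 3], 1)  # bin 3 -> 2

  flat <- flat_trace(2.0, 10)
  cflat <- traversal_matrix(flat)$counts
  expect_equal(cflat[21, 21], 99)
  expect_equal(sum(cflat), 99)

  expect_error(traversal_matrix(velocity_trace(0, 1)), class = "velozone_validation_error")
})

test_that("pairs spanning a cleaning gap are not counted", {
  v <- rep(3, 10); v[5] <- 11.5
  tr <- velocity_trace(times = 0:9 / 10, velocities = v)
  cleaned <- clean_trace(tr)$trace
  expect_length(cleaned$velocities, 9L)
  counts <- traversal_matrix(cleaned)$counts
  # 9 retained samples, 8 adjacent pairs, 2 of them touch the gap
  expect_equal(sum(counts), 7)
})

test_that("traversal totals equal the number of retained contiguous pairs", {
  for (seed in 1:5) {
    trace <- simulate_trace(four_state_model(spike_rate = 0.01), 120, seed = seed)
    cleaned <- clean_trace(trace)$trace
    n_pairs <- sum(abs(diff(cleaned$times) - 0.1) <= 1e-9)
    expect_equal(sum(traversal_matrix(cleaned)$counts), n_pairs)
  }
})

test_that("pooling is additive, commutative and grid-checked", {
  trace <- simulate_trace(four_state_model(), 60, seed = 1)
  M <- traversal_matrix(trace)
  zero <- structure(list(counts = matrix(0L, 100, 100), grid = bin_grid(),
                         source = "z"), class = "traversal_matrix")
  expect_equal(pool_traversals(list(M, zero))$counts, M$counts)
  expect_equal(pool_traversals(list(M, M))$counts, 2 * M$counts)
  B <- traversal_matrix(simulate_trace(four_state_model(), 60, seed = 2))
  expect_equal(pool_traversals(list(M, B))$counts, pool_traversals(list(B, M))$counts)
  expect_equal(pool_traversals(list(M, B))$source, "pooled")
  other_grid <- structure(list(counts = matrix(0L, 50, 50),
                               grid = bin_grid(0, 5, 0.1), source = "z"),
                          class = "traversal_matrix")
  expect_error(pool_traversals(list(M, other_grid)), class = "velozone_validation_error")
  expect_error(pool_traversals(list()), class = "velozone_validation_error")
})

test_that("the beta chain term floors the affinity and keeps degrees positive", {
  zero_T <- structure(list(counts = matrix(0L, 100, 100), grid = bin_grid(),
                           source = "z"), class = "traversal_matrix")
  A <- affinity_from_traversals(zero_T, beta = 0.1)
  offdiag <- abs(row(A$weights) - col(A$weights)) == 1
  expect_true(all(A$weights[offdiag] == 0.1))
  expect_true(all(A$weights[!offdiag] == 0))
  expect_true(all(rowSums(A$weights) > 0))

  single <- zero_T
  single$counts[6, 6] <- 10L
  A1 <- affinity_from_traversals(single)
  expect_equal(A1$weights[6, 6], 1.0)  # max-normalised data term
  expect_equal(A1$weights[6, 7], 0.1)  # chain term only off the diagonal

  expect_error(affinity_from_traversals(zero_T, beta = 0),
               class = "velozone_validation_error")
})

test_that("affinities are symmetric and scale-invariant for random count matrices", {
  for (seed in 1:100) {
    counts <- withr::with_seed(seed, matrix(rpois(400, 2), 20, 20))
    Tm <- structure(list(counts = counts, grid = bin_grid(0, 2, 0.1), source = "r"),
                    class = "traversal_matrix")
    A <- affinity_from_traversals(Tm)
    expect_identical(A$weights, t(A$weights))
    T2 <- Tm; T2$counts <- 2L * counts
    expect_equal(affinity_from_traversals(T2)$weights, A$weights, tolerance = 1e-12)
  }
})

test_that("the affinity graph is connected: one zero Laplacian eigenvalue", {
  trace <- simulate_trace(four_state_model(), 300, seed = 4)
  A <- affinity_from_traversals(traversal_matrix(trace))
  W <- A$weights
  L <- diag(rowSums(W)) - W
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8), 1L)
})

test_that("matrix serialisation writes a grid header and a square table", {
  dir <- withr::local_tempdir()
  trace <- simulate_trace(four_state_model(), 30, seed = 1)
  Tm <- traversal_matrix(trace)
  p1 <- file.path(dir, "trav.csv")
  write_matrix_csv(Tm, p1)
  lines <- readLines(p1)
  expect_match(lines[1], "^# traversal v_min=0 v_max=10 width=0.1")
  expect_length(lines, 101L)
  A <- affinity_from_traversals(Tm)
  p2 <- file.path(dir, "aff.csv")
  write_matrix_csv(A, p2)
  expect_match(readLines(p2, n = 1), "beta=0.1")
})
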